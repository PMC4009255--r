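# Biomarker trigger terms, seeded from the MeSH "Biological Markers"
# concept and its entry terms; edit freely, one term per line.
biomarker
biomarkers
biological marker
biological markers
biologic marker
biologic markers
marker
markers
clinical marker
clinical markers
laboratory marker
laboratory markers
serum marker
serum markers
surrogate marker
surrogate markers
surrogate endpoint
surrogate endpoints
immunologic marker
immunologic markers
immune marker
immune markers
viral marker
viral markers
tumor marker
tumor markers
tumour marker
tumour markers
biochemical marker
biochemical markers
molecular marker
molecular markers
prognostic marker
prognostic markers
diagnostic marker
diagnostic markers
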
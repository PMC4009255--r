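# Very general terms removed from dictionaries during curation.
disease
diseases
syndrome
syndromes
disorder
disorders
abnormality
abnormalities
deficiency
finding
findings
symptom
symptoms
infection
infections
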
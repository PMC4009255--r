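# Small English function-word list applied when compiling matcher patterns.
a
an
the
and
or
nor
not
was
were
is
are
be
been
being
of
in
on
at
by
for
with
to
from
as
that
this
these
those
it
its
we
our
can
could
may
might
will
would
should
have
has
had
but
than
then
which
who
whom
whose
all
any
each
also
into
after
before
between
during
per
via
such
other
more
most
less
least
no
only
over
under
both
about
against
same
so
too
very
what
when
where
while
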
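# Stop tokens ignored when building order-free token signatures.
# Core prepositions, articles, and a small quantifier set; one per line.
in
of
to
by
from
with
the
a
an
some
several
many
few
multiple
most
any
both
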
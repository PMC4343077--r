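# Quality head nouns (normalized form).  A coordination whose shared trailing
# token normalizes into this set is decomposed into nested suffix spans.
abnormality
hypoplasia
aplasia
dysplasia
hyperplasia
hypertrophy
atrophy
agenesis
synostosis
stenosis
defect
fusion
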
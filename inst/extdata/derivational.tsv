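surface	normal	pos
hypoplastic	hypoplasia	adj
aplastic	aplasia	adj
dysplastic	dysplasia	adj
hyperplastic	hyperplasia	adj
hypertrophic	hypertrophy	adj
atrophic	atrophy	adj
stenotic	stenosis	adj
agenetic	agenesis	adj
abnormal	abnormality	adj
anomalous	abnormality	adj
malformed	abnormality	adj
anomaly	abnormality	noun
malformation	abnormality	noun
otic	ear	adj
aural	ear	adj
behavior	behaviour	noun
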
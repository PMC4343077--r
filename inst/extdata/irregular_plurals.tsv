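plural	singular
vertebrae	vertebra
calvariae	calvaria
teeth	tooth
feet	foot
nares	naris
phalanges	phalanx
foramina	foramen
ganglia	ganglion
genua	genu
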
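taxonID	scientificName	scientificNameAuthorship	taxonRank	parentNameUsageID	acceptedNameUsageID	taxonomicStatus	family
f1	Moraceae		family			accepted	Moraceae
f2	Fucaceae		family			accepted	Fucaceae
f3	Poaceae		family			accepted	Poaceae
f4	Asteraceae		family			accepted	Asteraceae
g1	Ficus	L.	genus	f1		accepted	Moraceae
g2	Fucus	L.	genus	f2		accepted	Fucaceae
g3	Poa	L.	genus	f3		accepted	Poaceae
g4	Bromus	L.	genus	f3		accepted	Poaceae
g5	Chondrophora	Raf.	genus	f4		accepted	Asteraceae
s1	Ficus insipida	Willd.	species	g1		accepted	Moraceae
s2	Poa annua	L.	species	g3		accepted	Poaceae
s3	Poa infirma	Kunth	species	g3		accepted	Poaceae
s4	Poa supina	Schrad.	species	g3	s2	synonym	Poaceae
s5	Bromus inermis	Leyss.	species	g4		accepted	Poaceae
s6	Chondrophora nudata	(Michx.) Britton	species	g5		accepted	Asteraceae
i1	Bromus inermis var. confinis	(Nees ex Steud.) Stapf	variety	s5		accepted	Poaceae
i2	Chondrophora nudata var. virgata	(Nutt.) Britton	variety	s6		accepted	Asteraceae
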
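unit	negation	related_taxa	word_part	generality	homonym
Shark	2	7	1	2	0
Lion	0	4	2	0	0
Moss					
Diatom	0	1	1	2	0
Mosquito	0	0	0	0	0
Bacteria	0	1	1	3	1
Cactus	0	0	0	0	0
Oak	0	2	0	0	0
Worm	0	1	0	1	1
Crab	0	3	0	0	1
Spider	0	1	0	0	2
Ciliate	0	0	0	0	0
Mushroom	0	0	0	1	0
Beetle	0	0	0	0	0
Walrus	1	0	2	1	3
Water Bear	0	0	0	0	1
Copepod	0	0	0	0	0
Virus	0	0	0	0	0
Kelp	0	0	1	0	0
Tube Worm	1	1	1	0	1
Honey Bee	0	0	2	0	1
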
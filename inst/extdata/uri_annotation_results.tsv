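unit	scientific_name	taxon_id	n_objects	n_correct_uris	n_correct_unique_uris	precision	recall
Great White Shark	Carcharodon carcharias	213726	56	169	45	0.918	1
Lion	Panthera leo	328672	52	173	45	0.961	1
Moss	Hypnum fauriei	861365	2	0	0	0	0
Diatom	Pseudo-nitzschia australis	904440	19	23	14	0.852	1
Mosquito	Culex pipiens	740671	8	8	6	1	1
Bacteria	Escherichia coli	972688	7	36	17	0.783	1
Cactus	Harrisia simpsonii	594934	20	13	9	1	1
Oak	Quercus robur	1151323	36	37	20	0.949	1
Worm	Lumbricus terrestris	3126801	17	28	15	0.903	1
Crab	Callinectes sapidus	312939	45	94	36	0.95	1
Spider	Loxosceles reclusa	1182604	17	27	16	0.871	1
Ciliate	Paramecium aurelia	484359	2	3	3	1	1
Mushroom	Psilocybe cubensis	190054	9	9	7	0.9	1
Beetle	Oryctes nasicornis	982103	2	5	5	1	1
Walrus	Odobenus rosmarus	328627	57	100	35	0.909	1
Water Bear	Hypsibius dujardini	1053826	4	5	5	0.833	1
Virus	Tobacco mosaic virus	8615186	2	5	4	1	1
Copepod	Eurytemora affinis	1020941	6	6	4	1	1
Kelp	Nereocystis luetkeana	902899	9	7	5	0.875	1
Tube Worm	Riftia pachyptila	393274	55	68	17	0.523	1
Honey Bee	Apis mellifera	1045608	61	222	54	0.978	1
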
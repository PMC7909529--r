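# Curated KEGG-style pathway mini-library (static subset, urinary metabolites)
# pathway_id <TAB> name <TAB> members...
map00260	Glycine, serine and threonine metabolism	glycine	guanidinoacetate	betaine	dimethylglycine	sarcosine	creatine	L-serine	L-threonine	choline	pyruvate
map00970	Aminoacyl-tRNA biosynthesis	glycine	L-alanine	L-serine	L-threonine	L-valine	L-leucine	L-isoleucine	L-phenylalanine	L-tyrosine	L-histidine	L-glutamate	L-glutamine
map00010	Glycolysis / Gluconeogenesis	L-lactate	pyruvate	D-glucose	acetate
map00620	Pyruvate metabolism	pyruvate	L-lactate	acetate	formate	L-malate
map00250	Alanine, aspartate and glutamate metabolism	L-alanine	succinate	fumarate	pyruvate	L-aspartate	L-glutamate	L-glutamine
map00330	Arginine and proline metabolism	guanidinoacetate	creatine	creatinine	L-arginine	L-proline	L-ornithine	4-hydroxyproline
map00020	Citrate cycle (TCA cycle)	citrate	succinate	fumarate	pyruvate	L-malate	2-oxoglutarate
map00360	Phenylalanine metabolism	phenylacetylglycine	L-phenylalanine	hippurate	phenylacetate	L-tyrosine	phenylpyruvate
map00430	Taurine and hypotaurine metabolism	taurine	hypotaurine	L-cysteine	pyruvate	acetate
map00280	Valine, leucine and isoleucine degradation	L-valine	L-leucine	L-isoleucine	succinate	acetate
map00650	Butanoate metabolism	succinate	acetate	butyrate	3-hydroxybutyrate	pyruvate
map00760	Nicotinate and nicotinamide metabolism	N-methylnicotinamide	nicotinamide	nicotinate	fumarate
map00340	Histidine metabolism	L-histidine	histamine	formate	L-glutamate
map00680	Methane metabolism	formate	trimethylamine	dimethylamine	methanol
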
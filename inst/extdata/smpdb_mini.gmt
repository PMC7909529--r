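# Curated SMPDB-style pathway mini-library (static subset, urinary metabolites)
# pathway_id <TAB> name <TAB> members...
SMP00004	Glycine and Serine Metabolism	glycine	guanidinoacetate	creatine	dimethylglycine	sarcosine	betaine	L-serine	L-threonine	pyruvate	formate
SMP00020	Arginine and Proline Metabolism	guanidinoacetate	creatine	creatinine	L-arginine	L-ornithine	L-proline	L-glutamate
SMP00055	Alanine Metabolism	L-alanine	pyruvate	L-glutamate	2-oxoglutarate
SMP00040	Glycolysis	L-lactate	pyruvate	D-glucose
SMP00128	Gluconeogenesis	L-lactate	pyruvate	D-glucose	L-alanine	oxaloacetate
SMP00123	Betaine Metabolism	betaine	dimethylglycine	choline	sarcosine	glycine	L-serine
SMP00021	Taurine and Hypotaurine Metabolism	taurine	hypotaurine	L-cysteine	acetate
SMP00209	Phenylacetate Metabolism	phenylacetylglycine	phenylacetate	glycine	L-glutamine
SMP00057	Citric Acid Cycle	citrate	succinate	fumarate	pyruvate	oxaloacetate	2-oxoglutarate
SMP00008	Phenylalanine and Tyrosine Metabolism	L-phenylalanine	L-tyrosine	phenylpyruvate	hippurate
SMP00033	Lactose Degradation	D-glucose	D-galactose
SMP00044	Ketone Body Metabolism	3-hydroxybutyrate	acetoacetate	acetone
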
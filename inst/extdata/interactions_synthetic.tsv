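# Synthetic metabolite-interaction edge list (stand-in for a chemical
# interaction database extract; scores are plausible confidences, not measured)
node_a	node_b	score
glycine	guanidinoacetate	0.92
glycine	creatine	0.88
guanidinoacetate	creatine	0.95
creatine	creatinine	0.93
glycine	L-serine	0.91
glycine	sarcosine	0.89
sarcosine	dimethylglycine	0.87
dimethylglycine	betaine	0.90
betaine	choline	0.86
glycine	betaine	0.62
glycine	L-threonine	0.71
L-serine	L-threonine	0.68
L-serine	pyruvate	0.74
L-lactate	pyruvate	0.94
pyruvate	L-alanine	0.90
L-alanine	L-glutamate	0.72
pyruvate	acetate	0.69
pyruvate	citrate	0.66
citrate	succinate	0.78
succinate	fumarate	0.84
fumarate	L-malate	0.82
L-lactate	D-glucose	0.73
pyruvate	D-glucose	0.77
phenylacetylglycine	phenylacetate	0.93
phenylacetate	L-phenylalanine	0.85
phenylacetylglycine	glycine	0.81
L-phenylalanine	L-tyrosine	0.83
L-phenylalanine	phenylpyruvate	0.70
hippurate	glycine	0.64
hippurate	phenylacetate	0.49
taurine	hypotaurine	0.88
taurine	L-cysteine	0.63
guanidinoacetate	L-arginine	0.87
L-arginine	L-ornithine	0.85
L-ornithine	L-proline	0.67
creatinine	L-arginine	0.44
trimethylamine	dimethylamine	0.76
trimethylamine	choline	0.79
dimethylamine	methylguanidine	0.41
formate	pyruvate	0.52
formate	L-serine	0.47
N-methylnicotinamide	nicotinamide	0.91
nicotinamide	nicotinate	0.84
L-glutamate	L-glutamine	0.89
L-glutamate	2-oxoglutarate	0.80
2-oxoglutarate	succinate	0.75
L-alanine	glycine	0.58
L-lactate	L-alanine	0.61
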
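pathway	precursor	member
glycolysis	glucose	hexose_P
glycolysis	glucose	FBP
glycolysis	glucose	DHAP
glycolysis	glucose	PG3
glycolysis	glucose	PEP
glycolysis	glucose	pyruvate
glycolysis	glucose	lactate
glycolysis	glucose	ATP
glycolysis	glucose	NADH
pentose_phosphate	glucose	PG6
pentose_phosphate	glucose	R5P
pentose_phosphate	glucose	S7P
pentose_phosphate	glucose	E4P
pentose_phosphate	glucose	NADPH
tca_cycle	pyruvate	citrate
tca_cycle	pyruvate	aconitate
tca_cycle	pyruvate	isocitrate
tca_cycle	pyruvate	alpha_KG
tca_cycle	pyruvate	succinate
tca_cycle	pyruvate	fumarate
tca_cycle	pyruvate	malate
tca_cycle	pyruvate	lactate
tca_cycle	pyruvate	NADH
tca_cycle	pyruvate	NAD
tca_cycle	pyruvate	ATP
tca_cycle	pyruvate	NADPH
proline_metabolism	proline	glutamate
proline_metabolism	proline	P5C
proline_metabolism	proline	ornithine
proline_metabolism	proline	arginine
serine_metabolism	serine	glycine
serine_metabolism	serine	phosphoserine
serine_metabolism	serine	cystathionine
glutamine_metabolism	glutamine	glutamate
glutamine_metabolism	glutamine	aspartate
glutamine_metabolism	glutamine	asparagine
glutamine_metabolism	glutamine	alpha_KG
glutamine_metabolism	glutamine	GSH
methionine_metabolism	methionine	SAM
methionine_metabolism	methionine	SAH
methionine_metabolism	methionine	homocysteine
methionine_metabolism	methionine	cystathionine
methionine_metabolism	methionine	taurine
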
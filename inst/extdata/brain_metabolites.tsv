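id	name	compartment	exchanged
glc__D_e	D-glucose	extracellular	1
lac__L_e	L-lactate	extracellular	1
gln__L_e	L-glutamine	extracellular	1
pyr_e	Pyruvate	extracellular	1
o2_e	Oxygen	extracellular	1
co2_e	Carbon dioxide	extracellular	1
h2o_e	Water	extracellular	1
nh4_e	Ammonium	extracellular	1
glc__D_c	D-glucose	cytosolic	0
g6p_c	Glucose 6-phosphate	cytosolic	0
f6p_c	Fructose 6-phosphate	cytosolic	0
fdp_c	Fructose 1,6-bisphosphate	cytosolic	0
dhap_c	Dihydroxyacetone phosphate	cytosolic	0
g3p_c	Glyceraldehyde 3-phosphate	cytosolic	0
13dpg_c	1,3-bisphosphoglycerate	cytosolic	0
3pg_c	3-phosphoglycerate	cytosolic	0
2pg_c	2-phosphoglycerate	cytosolic	0
pep_c	Phosphoenolpyruvate	cytosolic	0
pyr_c	Pyruvate	cytosolic	0
lac__L_c	L-lactate	cytosolic	0
ru5p__D_c	Ribulose 5-phosphate (6-carbon-unit pool)	cytosolic	0
nadp_c	NADP+	cytosolic	0
nadph_c	NADPH	cytosolic	0
nad_c	NAD+	cytosolic	0
nadh_c	NADH	cytosolic	0
atp_c	ATP	cytosolic	0
adp_c	ADP	cytosolic	0
pi_c	Inorganic phosphate	cytosolic	0
h_c	Proton (cytosolic, not balanced)	cytosolic	1
h2o_c	Water	cytosolic	0
co2_c	Carbon dioxide	cytosolic	0
o2_c	Oxygen	cytosolic	0
nh4_c	Ammonium	cytosolic	0
gln__L_c	L-glutamine	cytosolic	0
glu__L_c	L-glutamate	cytosolic	0
asp__L_c	L-aspartate	cytosolic	0
oaa_c	Oxaloacetate	cytosolic	0
mal__L_c	L-malate	cytosolic	0
akg_c	Alpha-ketoglutarate	cytosolic	0
glyc3p_c	Glycerol 3-phosphate	cytosolic	0
4abut_c	4-aminobutanoate (GABA)	cytosolic	0
pyr_m	Pyruvate	mitochondrial	0
coa_m	Coenzyme A	mitochondrial	0
accoa_m	Acetyl-CoA	mitochondrial	0
co2_m	Carbon dioxide	mitochondrial	0
nad_m	NAD+	mitochondrial	0
nadh_m	NADH	mitochondrial	0
atp_m	ATP	mitochondrial	0
adp_m	ADP	mitochondrial	0
pi_m	Inorganic phosphate	mitochondrial	0
h_m	Proton (mitochondrial matrix, balanced)	mitochondrial	0
h2o_m	Water	mitochondrial	0
oaa_m	Oxaloacetate	mitochondrial	0
mal__L_m	L-malate	mitochondrial	0
cit_m	Citrate	mitochondrial	0
icit_m	Isocitrate	mitochondrial	0
akg_m	Alpha-ketoglutarate	mitochondrial	0
succoa_m	Succinyl-CoA	mitochondrial	0
succ_m	Succinate	mitochondrial	0
fum_m	Fumarate	mitochondrial	0
q10_m	Ubiquinone	mitochondrial	0
q10h2_m	Ubiquinol	mitochondrial	0
ficytc_m	Cytochrome c (oxidized)	mitochondrial	0
focytc_m	Cytochrome c (reduced)	mitochondrial	0
o2_m	Oxygen	mitochondrial	0
asp__L_m	L-aspartate	mitochondrial	0
glu__L_m	L-glutamate	mitochondrial	0
gln__L_m	L-glutamine	mitochondrial	0
nh4_m	Ammonium	mitochondrial	0
4abut_m	4-aminobutanoate (GABA)	mitochondrial	0
sucsal_m	Succinate semialdehyde	mitochondrial	0
h2o2_c	Hydrogen peroxide	cytosolic	0
gsh_c	Glutathione (reduced)	cytosolic	0
gssg_c	Glutathione (oxidized)	cytosolic	0
ala__L_c	L-alanine	cytosolic	0
ala__L_e	L-alanine	extracellular	1
gtp_m	GTP	mitochondrial	0
gdp_m	GDP	mitochondrial	0
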
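id	name	equation	reversible	subsystem	genes
GLCt1r	Glucose uptake from blood (GLUT)	glc__D_e <=> glc__D_c	1	transport	SLC2A1;SLC2A3
L_LACt2r	Lactate exchange with blood (MCT, uptake positive)	lac__L_e <=> lac__L_c	1	transport	SLC16A1;SLC16A7
GLNt	Glutamine exchange with blood (SNAT, uptake positive)	gln__L_e <=> gln__L_c	1	transport	SLC38A3;SLC38A5
PYRt2r	Pyruvate exchange with blood (MCT, uptake positive)	pyr_e <=> pyr_c	1	transport	SLC16A1
O2t	Oxygen uptake from blood (diffusion)	o2_e <=> o2_c	1	transport
CO2t	Carbon dioxide release to blood (diffusion)	co2_c <=> co2_e	1	transport
H2Ot	Water release to blood	h2o_c <=> h2o_e	1	transport
NH4t	Ammonium uptake from blood	nh4_e <=> nh4_c	1	transport
ALAt	Alanine release to blood	ala__L_c -> ala__L_e	0	transport
HEX1	Hexokinase	atp_c + glc__D_c -> adp_c + g6p_c + h_c	0	glycolysis	HK1;HK2;HK3
PGI	Glucose-6-phosphate isomerase	g6p_c <=> f6p_c	1	glycolysis	GPI
PFK	Phosphofructokinase	atp_c + f6p_c -> adp_c + fdp_c + h_c	0	glycolysis	PFKL;PFKM;PFKP
FBA	Fructose-bisphosphate aldolase	fdp_c <=> dhap_c + g3p_c	1	glycolysis	ALDOA;ALDOB;ALDOC
TPI	Triose-phosphate isomerase	dhap_c <=> g3p_c	1	glycolysis	TPI1
GAPD	Glyceraldehyde-3-phosphate dehydrogenase	g3p_c + nad_c + pi_c <=> 13dpg_c + h_c + nadh_c	1	glycolysis	GAPDH
PGK	Phosphoglycerate kinase	13dpg_c + adp_c <=> 3pg_c + atp_c	1	glycolysis	PGK1
PGM	Phosphoglycerate mutase	3pg_c <=> 2pg_c	1	glycolysis	PGAM1
ENO	Enolase	2pg_c <=> h2o_c + pep_c	1	glycolysis	ENO1;ENO2
PYK	Pyruvate kinase	adp_c + h_c + pep_c -> atp_c + pyr_c	0	glycolysis	PKM
PPP_OX	Pentose phosphate pathway, oxidative branch (lumped, 6-carbon units)	g6p_c + h2o_c + 2 nadp_c -> co2_c + 2 h_c + 2 nadph_c + ru5p__D_c	0	ppp	G6PD;PGLS;PGD
PPP_NONOX	Pentose phosphate pathway, non-oxidative return (lumped, 6-carbon units)	ru5p__D_c -> 0.6666666666666667 f6p_c + 0.3333333333333333 g3p_c	0	ppp	RPIA;RPE;TKT;TALDO1
NOX	NADPH oxidase (lumped superoxide/peroxide generation)	nadph_c + o2_c -> h2o2_c + nadp_c	0	antioxidant	NOX4;CYBB
GPX	Glutathione peroxidase	2 gsh_c + h2o2_c -> gssg_c + 2 h2o_c	0	antioxidant	GPX1;GPX4
GTHOr	Glutathione reductase	gssg_c + h_c + nadph_c -> 2 gsh_c + nadp_c	0	antioxidant	GSR
LDH_L	Lactate dehydrogenase	h_c + nadh_c + pyr_c <=> lac__L_c + nad_c	1	pyruvate	LDHA;LDHB
GPT	Alanine aminotransferase	glu__L_c + pyr_c <=> akg_c + ala__L_c	1	pyruvate	GPT;GPT2
ME1	Malic enzyme (NADP), cytosolic	mal__L_c + nadp_c -> co2_c + nadph_c + pyr_c	0	pyruvate	ME1
PYRt2m	Pyruvate transport, mitochondrial (MPC)	pyr_c <=> pyr_m	1	transport	MPC1;MPC2
PDHm	Pyruvate dehydrogenase	coa_m + nad_m + pyr_m -> accoa_m + co2_m + nadh_m	0	pyruvate	PDHA1;PDHB;DLAT;DLD
PCm	Pyruvate carboxylase	atp_m + co2_m + h2o_m + pyr_m -> adp_m + oaa_m + pi_m	0	pyruvate	PC
ME2m	Malic enzyme (NAD), mitochondrial	mal__L_m + nad_m -> co2_m + nadh_m + pyr_m	0	pyruvate	ME2;ME3
CSm	Citrate synthase	accoa_m + h2o_m + oaa_m -> cit_m + coa_m	0	tca	CS
ACONTm	Aconitase	cit_m <=> icit_m	1	tca	ACO2
ICDHxm	Isocitrate dehydrogenase (NAD)	icit_m + nad_m -> akg_m + co2_m + nadh_m	0	tca	IDH3A;IDH3B;IDH3G
AKGDm	Alpha-ketoglutarate dehydrogenase	akg_m + coa_m + nad_m -> co2_m + nadh_m + succoa_m	0	tca	OGDH;DLST;DLD
SUCOAS1m	Succinyl-CoA ligase (GDP-forming)	gdp_m + pi_m + succoa_m <=> coa_m + gtp_m + succ_m	1	tca	SUCLG1;SUCLG2
NDPK1m	Nucleoside-diphosphate kinase, mitochondrial	adp_m + gtp_m <=> atp_m + gdp_m	1	tca	NME4
SUCDm	Succinate dehydrogenase (complex II)	q10_m + succ_m -> fum_m + q10h2_m	0	tca	SDHA;SDHB;SDHC;SDHD
FUMm	Fumarase	fum_m + h2o_m <=> mal__L_m	1	tca	FH
MDHm	Malate dehydrogenase, mitochondrial	mal__L_m + nad_m <=> h_m + nadh_m + oaa_m	1	tca	MDH2
NADH2_u10mi	NADH dehydrogenase (complex I)	5 h_m + nadh_m + q10_m -> 4 h_c + nad_m + q10h2_m	0	oxphos	ND1;ND2;ND3;ND4;ND4L;ND5;ND6;NDUFS1;NDUFV1
CYOR_u10mi	Ubiquinol-cytochrome c reductase (complex III)	2 ficytc_m + 2 h_m + q10h2_m -> 2 focytc_m + 4 h_c + q10_m	0	oxphos	CYTB;UQCRC1;UQCRC2;UQCRFS1;CYC1
CYOOm3i	Cytochrome c oxidase (complex IV)	4 focytc_m + 8 h_m + o2_m -> 4 ficytc_m + 4 h_c + 2 h2o_m	0	oxphos	COX1;COX2;COX3;COX4I1;COX5A
ATPS4mi	ATP synthase (F1Fo)	adp_m + 4 h_c + pi_m -> atp_m + h2o_m + 3 h_m	0	oxphos	ATP6;ATP8;ATP5F1A;ATP5F1B;ATP5MC1
Htm	Inner-membrane proton leak (uncoupling)	h_c -> h_m	0	oxphos	SLC25A27
ATPtm	ADP/ATP translocase (ANT)	adp_c + atp_m <=> adp_m + atp_c	1	transport	SLC25A4;SLC25A5;SLC25A6
PIt2m	Phosphate carrier, mitochondrial	h_c + pi_c <=> h_m + pi_m	1	transport	SLC25A3
DICtm	Dicarboxylate carrier (malate/phosphate antiport)	mal__L_c + pi_m <=> mal__L_m + pi_c	1	transport	SLC25A10
O2tm	Oxygen diffusion, mitochondrial	o2_c <=> o2_m	1	transport
CO2tm	Carbon dioxide diffusion, mitochondrial	co2_m <=> co2_c	1	transport
H2Otm	Water transport, mitochondrial	h2o_m <=> h2o_c	1	transport
ASPTA	Aspartate aminotransferase, cytosolic	akg_c + asp__L_c <=> glu__L_c + oaa_c	1	shuttle	GOT1
MDH	Malate dehydrogenase, cytosolic	mal__L_c + nad_c <=> h_c + nadh_c + oaa_c	1	shuttle	MDH1
AKGMALtm	Alpha-ketoglutarate/malate antiporter	akg_m + mal__L_c <=> akg_c + mal__L_m	1	shuttle	SLC25A11
ASPGLUm	Aspartate/glutamate carrier (electrogenic, proton-compensated)	asp__L_m + glu__L_c + h_c -> asp__L_c + glu__L_m + h_m	0	shuttle	SLC25A12;SLC25A13
ASPTAm	Aspartate aminotransferase, mitochondrial	akg_m + asp__L_m <=> glu__L_m + oaa_m	1	shuttle	GOT2
G3PD2	Glycerol-3-phosphate dehydrogenase (NAD), cytosolic	dhap_c + h_c + nadh_c -> glyc3p_c + nad_c	0	shuttle	GPD1
G3PDm	Glycerol-3-phosphate dehydrogenase (FAD), mitochondrial	glyc3p_c + q10_m -> dhap_c + q10h2_m	0	shuttle	GPD2
GLUDC	Glutamate decarboxylase	glu__L_c + h_c -> 4abut_c + co2_c	0	gaba_shunt	GAD1;GAD2
ABUTtm	GABA transport, mitochondrial	4abut_c <=> 4abut_m	1	gaba_shunt
ABTArm	GABA transaminase	4abut_m + akg_m <=> glu__L_m + sucsal_m	1	gaba_shunt	ABAT
SSALxm	Succinate-semialdehyde dehydrogenase	h2o_m + nad_m + sucsal_m -> h_m + nadh_m + succ_m	0	gaba_shunt	ALDH5A1
GLNS	Glutamine synthetase	atp_c + glu__L_c + nh4_c -> adp_c + gln__L_c + h_c + pi_c	0	gln_cycle	GLUL
GLNtm	Glutamine transport, mitochondrial	gln__L_c <=> gln__L_m	1	gln_cycle
GLUNm	Glutaminase	gln__L_m + h2o_m -> glu__L_m + nh4_m	0	gln_cycle	GLS;GLS2
GLUt2m	Glutamate carrier, mitochondrial (glutamate/OH- antiport, export)	glu__L_m + h_m -> glu__L_c + h_c	0	gln_cycle	SLC25A18;SLC25A22
GLUDxm	Glutamate dehydrogenase (NAD)	glu__L_m + h2o_m + nad_m <=> akg_m + h_m + nadh_m + nh4_m	1	gln_cycle	GLUD1;GLUD2
NH4tm	Ammonium transport, mitochondrial	nh4_c <=> nh4_m	1	transport
ATPM	ATP demand (ion pumping and maintenance)	atp_c + h2o_c -> adp_c + h_c + pi_c	0	demand
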
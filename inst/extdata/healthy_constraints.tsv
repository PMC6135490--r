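reaction_id	type	value	reference_id
GLCt1r	fixed	0.203
L_LACt2r	fixed	-0.0092
GLNt	fixed	-0.011
PYRt2r	fixed	-0.0024
PPP_OX	ratio	0.069	HEX1
PCm	ratio	0.13	GLCt1r
GLUNm	ratio	0.62	GLCt1r
GLUDC	ratio	0.32	GLCt1r
ATPS4mi	objective	1
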
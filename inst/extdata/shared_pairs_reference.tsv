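gene1	gene2	r_case_ra	r_control_ra	r_case_pd	r_control_pd
ARHGAP17	TSHZ3	0.382	-0.561	0.384	-0.497
CDK20	GRB2	0.481	-0.484	0.517	-0.492
CDK20	PLEKHF2	0.458	-0.342	0.492	-0.408
CRY1	GRB2	0.599	-0.252	0.552	-0.264
ETV1	GRB2	0.368	-0.473	0.63	-0.237
GATA3	GRB2	0.279	-0.544	0.59	-0.64
GRB2	LCA5	0.505	-0.36	0.469	-0.41
GRB2	PVR	0.692	-0.32	0.698	-0.114
GRB2	TSHZ3	0.441	-0.616	0.397	-0.588
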
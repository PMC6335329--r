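interval	case_[-1,-0.75)	case_[-0.75,-0.5)	case_[-0.5,-0.25)	case_[-0.25,0)	case_[0,0.25)	case_[0.25,0.5)	case_[0.5,0.75)	case_[0.75,1]
control_[-1,-0.75)	77481	27809	80	2	0	0	0	0
control_[-0.75,-0.5)	7299	764774	1286473	68700	108	5	0	0
control_[-0.5,-0.25)	2	182660	5696562	7398531	482134	956	13	0
control_[-0.25,0)	0	1753	1784109	27223563	20688414	650691	716	0
control_[0,0.25)	0	2	26663	8265509	59694607	19289656	245055	50
control_[0.25,0.5)	0	0	30	50725	8254707	35908516	8184266	3747
control_[0.5,0.75)	0	0	0	11	15739	3231110	13539841	702925
control_[0.75,1]	0	0	0	0	0	577	408604	1074525
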
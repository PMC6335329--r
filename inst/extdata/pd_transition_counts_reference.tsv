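interval	case_[-1,-0.75)	case_[-0.75,-0.5)	case_[-0.5,-0.25)	case_[-0.25,0)	case_[0,0.25)	case_[0.25,0.5)	case_[0.5,0.75)	case_[0.75,1]
control_[-1,-0.75)	53560	7274	0	0	0	0	0	0
control_[-0.75,-0.5)	6062	58463	4277	9	2	0	0	0
control_[-0.5,-0.25)	3	24024	85156	16583	314	5	1	0
control_[-0.25,0)	9	16305	484685	2012234	1168009	12571	33	0
control_[0,0.25)	6	5546	393274	7360253	29846001	5438956	33073	57
control_[0.25,0.5)	0	594	73877	2210173	29393376	58680360	5410454	4552
control_[0.5,0.75)	0	13	1807	111235	2805248	33491914	40651108	675825
control_[0.75,1]	0	0	2	60	3064	85461	2828820	1785012
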
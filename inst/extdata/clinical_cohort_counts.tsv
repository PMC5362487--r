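variable	level	microarray_n	validation_n
histological_classification	usual_scc	20	33
histological_classification	mixed	1	3
histological_classification	papillary	2	0
histological_grade	I	5	12
histological_grade	II	9	17
histological_grade	III	7	7
histological_grade	not_informed	2	0
hpv_infection	positive	7	9
hpv_infection	negative	16	27
lymph_node_metastasis	presence	9	13
lymph_node_metastasis	absence	13	21
lymph_node_metastasis	not_determined	1	2
perineural_invasion	presence	5	13
perineural_invasion	absence	18	23
t_stage	T1_2	14	22
t_stage	T3_4	9	14
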
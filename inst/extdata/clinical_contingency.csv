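contrast,factor,dataset,p_level1,p_level2,pm_level1,pm_level2
d1_stage,stage,D1,22,8,10,20
d2_stage,stage,D2,14,11,10,20
d1_sex,sex,D1,20,10,17,13
d1_tissue,tissue,D1,28,2,25,5
d3_tissue,tissue,D3,22,3,25,5
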
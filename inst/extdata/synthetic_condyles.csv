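subject_id,side,subcortical_sclerosis,surface_flattening,subcortical_cyst,erosion,osteophyte,generalized_sclerosis,hypoplasia,short_condyle
P001,left,0,0,0,0,0,0,0,0
P001,right,0,0,0,0,0,0,0,0
P002,left,0,0,0,0,0,0,0,0
P002,right,0,0,0,0,0,0,0,0
P003,left,0,0,0,0,0,0,0,0
P003,right,0,0,0,0,0,0,0,0
P004,left,0,0,0,0,0,0,0,0
P004,right,0,0,0,0,0,0,0,0
P005,left,0,0,0,0,0,0,0,0
P005,right,0,0,0,0,0,0,0,0
P006,left,0,0,0,0,0,0,0,0
P006,right,0,0,0,0,0,0,0,0
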
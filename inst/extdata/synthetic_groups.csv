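subject_id,group
S001,normal
S002,normal
S003,indeterminate
S004,indeterminate
S005,osteoarthrosis
S006,osteoarthrosis
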
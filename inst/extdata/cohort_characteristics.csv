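covariate,level,positive,negative
gender,male,231,109
gender,female,222,98
age_group,3-6,250,66
age_group,7-14,203,141
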
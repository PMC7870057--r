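clone_id	condition	wells_total	populated_wells	sensitive_wells	nominal_lambda
rRNA_promoter	non-induced	96	71	0	1.5
rRNA_promoter	induced	96	76	6	1.5
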
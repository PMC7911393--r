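method,mtv_e1,mtv_e2
suv2.5,774,760
percent41,324,241
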
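method,cutoff_1,cutoff_2
suv2.5,548,555
percent41,324,252
liver_max,483,500
percist,426,465
daisne,334,345
nestle,398,386
fitting,360,335
black,379,427
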
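method,class,mean_obs1,mean_obs2
suv2.5,absolute,1017.02,1023.15
percent41,percent,512.37,440.65
liver_max,absolute,907.61,905.03
percist,absolute,905.84,899.24
daisne,adaptive,474.19,432.00
nestle,adaptive,569.24,551.95
fitting,adaptive,623.27,546.74
black,adaptive,813.05,794.46
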
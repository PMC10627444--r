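subgroup,n_units,mean_total,sd_total
western,5,8.60,1.14
eastern,3,3.33,2.08
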
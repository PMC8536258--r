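# n_scored: 115
# total_ec: 66
# total_fsc: 29
category,n,mean_ec,mean_fsc
EC_only,11,3,
EC_FSC,8,3.5,2.625
FSC_only,2,,4
FC_only,3,,
EC_plus_FC,2,2.5,
unlabeled,89,,
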
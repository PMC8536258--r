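# n_scored: 73
# total_ec: 496
# total_fsc: 190
category,n,mean_ec,mean_fsc
EC_only,28,5.1,
EC_FSC,35,8.3,5.4
FSC_only,1,,7
FC_only,2,,
EC_plus_FC,7,9,
unlabeled,0,,
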
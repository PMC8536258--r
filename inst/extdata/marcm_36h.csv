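# n_scored: 129
# total_ec: 276
# total_fsc: 111
category,n,mean_ec,mean_fsc
EC_only,25,2.5,
EC_FSC,28,2.8,3.5
FSC_only,4,,3.25
FC_only,11,,
EC_plus_FC,53,2.6,
unlabeled,8,,
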
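# n_scored: 207
# total_ec: 253
# total_fsc: 111
category,n,mean_ec,mean_fsc
EC_only,46,2.4,
EC_FSC,24,4,4
FSC_only,3,,4.6666667
FC_only,9,,
EC_plus_FC,16,2.9,
unlabeled,109,,
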
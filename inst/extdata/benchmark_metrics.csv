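model,precision,recall,f1,f2,f0_5,accuracy
rules,0.861,0.815,0.837,0.824,0.851,0.961
bert,0.909,0.789,0.845,0.810,0.882,0.965
cbert,0.861,0.816,0.838,0.825,0.852,0.961
bert_ds,0.865,0.842,0.853,0.847,0.860,0.965
cbert_ds,0.892,0.868,0.880,0.873,0.887,0.971
bert_dsh,0.914,0.842,0.877,0.855,0.899,0.971
cbert_dsh,0.942,0.868,0.904,0.882,0.926,0.978
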
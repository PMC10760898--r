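stratum_id,threshold_nonfood_pct,threshold_total_pct
Barisal (Rural),30.10,16.76
Barisal (Urban),27.13,14.83
Chittagong (Rural),20.38,10.18
Chittagong (Urban),27.29,15.88
Chittagong (City Corp.),23.55,13.41
Dhaka (Rural),22.09,11.07
Dhaka (Urban),21.69,11.26
Dhaka (City Corp.),22.51,10.95
Khulna (Rural),25.66,13.36
Khulna (Urban),24.66,13.29
Khulna (City Corp.),17.18,9.30
Rajshahi (Rural),23.91,12.58
Rajshahi (Urban),24.19,12.46
Rajshahi (City Corp.),15.48,8.31
Sylhet (Rural),20.39,8.96
Sylhet (Urban),23.78,11.58
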
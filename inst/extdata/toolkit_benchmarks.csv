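method,n_features_selected,time_s_per_scan,redundancy_rate_pct,storage_gb,stability_score_pct
pyradiomics,1800,210,45.2,5.2,75.0
captk,1400,270,38.7,6.1,78.0
ibsi,1100,190,41.5,4.8,80.0
lifex,1200,220,39.2,5.5,79.0
serfe,350,95,15.4,2.8,92.0
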
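region,baseline_bn,delta_pv_bn
East Coast,1.519,-0.116
Gulf Coast,0.567,1.130
West Coast,0.443,-1.988
Alaska,1.247,-0.649
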
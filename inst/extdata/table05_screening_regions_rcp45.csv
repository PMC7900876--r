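region,baseline_bn,delta_pv_bn
East Coast,1.519,0.415
Gulf Coast,0.567,0.472
West Coast,0.443,-1.327
Alaska,1.247,-0.598
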
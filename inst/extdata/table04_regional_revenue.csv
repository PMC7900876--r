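region,all_fisheries_bn,matched_bn,matched_pct
East Coast,1.906,1.519,79.7
Gulf Coast,0.885,0.567,64.1
Subtotal: Atlantic,2.792,2.086,74.7
West Coast,0.693,0.443,63.9
Alaska,1.848,1.247,67.5
Subtotal: Pacific,2.541,1.689,66.5
Total,5.333,3.775,70.8
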
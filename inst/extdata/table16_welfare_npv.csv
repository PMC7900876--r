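group,npv_rcp45_mm,npv_rcp85_mm
Lobster/crab,-2126,-2848.2
Shrimp/mollusk,265.7,1469.7
High-value fish,-585.1,441.2
Low-value fish,355.8,-3292
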
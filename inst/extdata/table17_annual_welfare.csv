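year,welfare_rcp45_mm,welfare_rcp85_mm
2020,-1.18,-0.55
2030,-14.21,-7.29
2040,-44.21,-56.45
2050,-75.82,-109.59
2060,-118.90,-215.36
2070,-164.22,-329.27
2080,-200.60,-504.22
2090,-238.51,-693.10
2100,-277.94,-901.25
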
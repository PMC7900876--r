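fishery,mean_mm,sd_mm,delta_pv_mm
American lobster,502.5,111.5,54.1
Sea scallop,501.4,72.8,410.4
Walleye pollock,390.4,49.9,79.9
White shrimp,246.3,30.1,670.2
Brown shrimp,216.2,51.6,-133.3
Pacific cod,212.1,56.9,13
Blue crab,209.4,19.6,407.8
Dungeness crab,186.1,48,-800.4
Pacific halibut,182.9,60.3,52
Sablefish,140,27.3,227.6
Snow crab,113,38.4,-1048.4
Chum salmon,73.3,20.1,-210.9
California market squid,58,22,132.3
Chinook salmon,51.8,15.1,-36.3
Yellowfin sole,49.2,10.5,-180.4
Pacific hake,46.6,17.9,-51.6
Ocean shrimp,34.2,20.6,-185
Summer flounder,31.3,3.6,80.7
Longfin squid,29.7,9.2,79.3
Florida stone crab (claws),28.7,5,-164.9
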
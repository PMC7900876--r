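fishery,mean_mm,sd_mm,delta_pv_mm
American lobster,502.5,111.5,-219.9
Sea scallop,501.4,72.8,-114.3
Walleye pollock,390.4,49.9,189.9
White shrimp,246.3,30.1,1269.8
Brown shrimp,216.2,51.6,-176.5
Pacific cod,212.1,56.9,26.8
Blue crab,209.4,19.6,649.2
Dungeness crab,186.1,48,-1160.5
Pacific halibut,182.9,60.3,28.9
Sablefish,140,27.3,403.6
Snow crab,113,38.4,-1549.8
Chum salmon,73.3,20.1,-425.6
California market squid,58,22,205.7
Chinook salmon,51.8,15.1,24.3
Yellowfin sole,49.2,10.5,-349
Pacific hake,46.6,17.9,-78.5
Ocean shrimp,34.2,20.6,-258.2
Summer flounder,31.3,3.6,82.4
Longfin squid,29.7,9.2,76
Florida stone crab (claws),28.7,5,-204.3
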
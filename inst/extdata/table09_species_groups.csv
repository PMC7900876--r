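fishery,mean_mm,sd_mm,rank,group
American lobster,502.5,111.5,1,Lobster/crab
Sea scallop,501.4,72.8,2,Shrimp/mollusk
Walleye pollock,390.4,49.9,3,Low-value fish
White shrimp,246.3,30.1,4,Shrimp/mollusk
Brown shrimp,216.2,51.6,5,Shrimp/mollusk
Pacific cod,212.1,56.9,6,Low-value fish
Blue crab,209.4,19.6,7,Lobster/crab
Dungeness crab,186.1,48,8,Lobster/crab
Pacific halibut,182.9,60.3,9,High-value fish
Sablefish,140,27.3,10,High-value fish
Chum salmon,73.3,20.1,12,Low-value fish
California market squid,58,22,13,Shrimp/mollusk
Chinook salmon,51.8,15.1,14,High-value fish
Yellowfin sole,49.2,10.5,15,Low-value fish
Summer flounder,31.3,3.6,18,High-value fish
Florida stone crab (claws),28.7,5,20,Lobster/crab
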
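group,fishery,baseline_mmlb,landings_2050_mmlb,pct_2050,landings_2090_mmlb,pct_2090
Lobster/crab,Blue crab,168.3,179.1,6.4,250.5,48.9
Lobster/crab,Dungeness crab,58.9,45.6,-22.5,23,-60.9
Lobster/crab,American lobster,126.7,129.2,1.9,101.5,-19.9
Lobster/crab,Florida stone crab (claws),4.6,3.3,-29.3,2.1,-54
Shrimp/mollusk,Sea scallop,49.3,51.2,3.8,39.5,-20
Shrimp/mollusk,Brown shrimp,107.4,103.4,-3.7,101.9,-5.2
Shrimp/mollusk,White shrimp,109.1,127.8,17.1,161.8,48.2
Shrimp/mollusk,California market squid,179.4,201.6,12.3,241.4,34.6
High-value fish,Pacific halibut,43.2,44.1,2.1,39.4,-8.7
High-value fish,Sablefish,39.6,45.1,13.8,42.8,8.1
High-value fish,Chinook salmon,14.5,14.8,2.5,15.4,6.2
High-value fish,Summer flounder,11.2,12.3,9.2,14.5,28.8
Low-value fish,Walleye pollock,2760.6,2840.4,2.9,2733.3,-1
Low-value fish,Pacific cod,620.2,633.9,2.2,582.8,-6
Low-value fish,Yellowfin sole,290.6,213.3,-26.6,92.5,-68.2
Low-value fish,Chum salmon,118.7,95.1,-19.8,41.9,-64.7
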
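group,fishery,baseline_mmlb,landings_2050_mmlb,pct_2050,landings_2090_mmlb,pct_2090
Lobster/crab,Blue crab,168.3,180.1,7.1,194.5,15.6
Lobster/crab,Dungeness crab,58.9,49.2,-16.5,41,-30.4
Lobster/crab,American lobster,126.7,128.3,1.3,121.1,-4.4
Lobster/crab,Florida stone crab (claws),4.6,3.5,-25.1,3,-35.6
Shrimp/mollusk,Sea scallop,49.3,51.5,4.3,49.2,-0.3
Shrimp/mollusk,Brown shrimp,107.4,104.8,-2.5,102.7,-4.4
Shrimp/mollusk,White shrimp,109.1,120.8,10.7,127.7,17
Shrimp/mollusk,California market squid,179.4,193.9,8,215,19.8
High-value fish,Pacific halibut,43.2,43.1,-0.2,44.8,3.6
High-value fish,Sablefish,39.6,42.1,6.2,44.6,12.5
High-value fish,Chinook salmon,14.5,13.9,-3.7,14.3,-0.8
High-value fish,Summer flounder,11.2,12.4,10.2,13,15.6
Low-value fish,Walleye pollock,2760.6,2765.1,0.2,2840.3,2.9
Low-value fish,Pacific cod,620.2,616.4,-0.6,631.2,1.8
Low-value fish,Yellowfin sole,290.6,257.7,-11.3,200.4,-31
Low-value fish,Chum salmon,118.7,106.8,-10.1,84.5,-28.8
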
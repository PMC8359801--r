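Obs,Photo,Cond,Ci,Trmmol,PARi,Fs,Fm',CO2R,Tleaf,VpdL,plant_id,genotype,o2_fraction
1,25.172,0.2,280,2,1000,686.75,1000,400,21.4,0.84,WT_leaf1,WT,0.02
2,24.692,0.2,280,2,1000,699.02,1000,400,21.4,0.84,WT_leaf1,WT,0.02
3,25.058,0.2,280,2,1000,670.45,1000,400,21.4,0.84,WT_leaf1,WT,0.02
4,23.508,0.2,280,2,750,616.86,1000,400,21.4,0.84,WT_leaf1,WT,0.02
5,23.333,0.2,280,2,750,598.26,1000,400,21.4,0.84,WT_leaf1,WT,0.02
6,22.778,0.2,280,2,750,600.03,1000,400,21.4,0.84,WT_leaf1,WT,0.02
7,20.39,0.2,280,2,500,511.11,1000,400,21.4,0.84,WT_leaf1,WT,0.02
8,20.304,0.2,280,2,500,505.24,1000,400,21.4,0.84,WT_leaf1,WT,0.02
9,20.644,0.2,280,2,500,494.43,1000,400,21.4,0.84,WT_leaf1,WT,0.02
10,15.59,0.2,280,2,300,393.57,1000,400,21.4,0.84,WT_leaf1,WT,0.02
11,15.61,0.2,280,2,300,386.62,1000,400,21.4,0.84,WT_leaf1,WT,0.02
12,15.513,0.2,280,2,300,390.83,1000,400,21.4,0.84,WT_leaf1,WT,0.02
13,11.636,0.2,280,2,200,313.26,1000,400,21.4,0.84,WT_leaf1,WT,0.02
14,11.635,0.2,280,2,200,314.77,1000,400,21.4,0.84,WT_leaf1,WT,0.02
15,10.939,0.2,280,2,200,304.94,1000,400,21.4,0.84,WT_leaf1,WT,0.02
16,6.687,0.2,280,2,100,239.94,1000,400,21.4,0.84,WT_leaf1,WT,0.02
17,6.467,0.2,280,2,100,254.79,1000,400,21.4,0.84,WT_leaf1,WT,0.02
18,6.348,0.2,280,2,100,240.1,1000,400,21.4,0.84,WT_leaf1,WT,0.02
19,2.808,0.2,280,2,50,221.37,1000,400,21.4,0.84,WT_leaf1,WT,0.02
20,3.256,0.2,280,2,50,224.7,1000,400,21.4,0.84,WT_leaf1,WT,0.02
21,2.95,0.2,280,2,50,205.34,1000,400,21.4,0.84,WT_leaf1,WT,0.02
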
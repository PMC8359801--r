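Obs,Photo,Cond,Ci,Trmmol,PARi,Fs,Fm',CO2R,Tleaf,VpdL,plant_id,genotype,o2_fraction
1,17.269,0.2,280,2,1000,670.92,1000,400,21.4,0.84,WT_leaf1,WT,0.21
2,17.723,0.2,280,2,1000,677.99,1000,400,21.4,0.84,WT_leaf1,WT,0.21
3,17.381,0.2,280,2,1000,689.13,1000,400,21.4,0.84,WT_leaf1,WT,0.21
4,-0.953,0.2,280,2,0,NA,NA,400,21.4,0.84,WT_leaf1,WT,0.21
5,-0.965,0.2,280,2,0,NA,NA,400,21.4,0.84,WT_leaf1,WT,0.21
6,-0.973,0.2,280,2,0,NA,NA,400,21.4,0.84,WT_leaf1,WT,0.21
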
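# Column mapping for Li-cor 6400 text exports: canonical field -> file header
A: Photo
gs: Cond
Ci: Ci
E: Trmmol
I: PARi
Fs: Fs
Fm_prime: "Fm'"
obs: Obs
co2_ref: CO2R
leaf_temp: Tleaf
vpd: VpdL
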
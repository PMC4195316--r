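# transmission frontier of a 50-encoder population, one seed, short runs
model: ideal
a: 1
F_eff_grid: [10, 20]
'N': 50
duration_s: 20
cutoff_range: [2, 50]
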
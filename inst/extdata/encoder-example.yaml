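# 10 ideal-IF encoders, heterogeneous carriers around 40 spikes/s,
# full-depth modulation by 20-Hz band-limited noise, 30 s per seed.
kind: encoder
'N': 10
F0in: 40
carrier_v: 0.5
a: 1
cutoff: 20
duration_s: 30
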
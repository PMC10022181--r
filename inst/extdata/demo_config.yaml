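# small demonstration configuration for `crossblup pipeline`
seed: 42
n_chromosomes: 3
markers_per_chr: 200
fst: 0.15
n_sires_B: 8
n_dams_H: 120
progeny_per_sire: 15
purebred_generations: 2
n_founders_B: 40
n_founders_H: 80
n_pens: 4
n_hys: 4
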
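# spatial extent scan of excitation and inhibition
experiment: spatial_extent
fractions: [0.025, 0.05, 0.1, 0.2, 0.4, 0.7, 1.0]
n_basal: 50
n_tuft: 30
sigma: 9
reps: 20
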
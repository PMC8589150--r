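# basal x tuft synapse-count grid: burst classes
experiment: synapse_grid
n_basal_grid: [0, 50, 100, 150, 200, 250, 300]
n_tuft_grid: [0, 20, 40, 60, 80, 100, 120]
sigma: 10
dt: 0
reps: 20
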
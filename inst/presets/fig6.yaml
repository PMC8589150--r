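# calcium-dependent plasticity maps under timed inhibition
experiment: plasticity
loci: [1, 2, 3]
dt_inh_grid: {from: -20, to: 20, by: 5}
n_basal: 70
n_tuft: 40
sigma: 10
repetitions: 10
theta_p: 0.4
theta_d: 0.25
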
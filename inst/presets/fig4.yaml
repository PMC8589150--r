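# inhibition loci 1-9, single-branch tuft excitation
experiment: inhibition
locations: [1, 2, 3, 4, 5, 6, 7, 8, 9]
dt_inh_grid: [0]
n_basal: 70
n_tuft: 40
single_branch: true
sigma: 10
n_inh: 20
reps: 20
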
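# iso-distance inhibition strips, whole-tuft excitation
experiment: inhibition
strips: [{distance: 100, window: 200}, {distance: 950, window: 200},
         {distance: 1150, window: 200}]
dt_inh_grid: [-10, 0, 10]
n_basal: 70
n_tuft: 40
single_branch: false
sigma: 10
n_inh: 20
reps: 20
batches: {n: 10, size: 20}
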
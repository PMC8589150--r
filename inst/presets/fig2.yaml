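# basal-tuft delay window scan over temporal jitter
experiment: sigma_dt
n_basal: 50
n_tuft: 30
sigmas: [3, 6, 9, 12]
dt_grid: {from: -40, to: 40, by: 5}
reps: 20
vgcc_knockout_companion: true
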
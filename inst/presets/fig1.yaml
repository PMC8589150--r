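# burst initiation by basal and tuft input: example traces and thresholds
experiment: traces
n_basal: 50
n_tuft: 30
sigmas: [0, 3, 6, 9]
dt: 0
tuft_stretch: 750
reps: 20
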
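# factorial bias study: small demonstration grid
delta: [0.3]
sigma_b2: 0.6
sigma_eta2: [0.5, 0.75]
n_x: [10, 30]
n_y: 30
n_reps: 50
family: linear
methods: [naive, gbs, cgbs]
seed: 1
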
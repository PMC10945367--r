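# Demonstration configuration for run_stage(); see ?default_config for the
# meaning and documented range of every parameter.
seed: 1
n_species: 20
proteome_size: 200
mutation_rate: 0.1
n_neg: 200
n_otus: 60
n_samples: 200
block_strength: 0.9
n_core: 5
e_threshold: 1.0e-5
k_folds: 5
alpha: 0.05
rho_min: 0.58
p_max: 0.05
min_shared: 2
min_languages: 5
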
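# Example pipeline configuration (see read_run_config())
input_dir: study
output_dir: out
model: m3.3^251
chains: 4
iter: 5000
burn: 1000
thin: 10
seed: 1
n_colonies: 6
n_draws: 200
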
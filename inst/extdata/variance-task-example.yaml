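# Example declarative model specification for the CLI:
#   Rscript inst/cli/nlcc.R simulate-v1 --config variance-task-example.yaml \
#     --out session.csv --seed 1
model: variance_task
sigma_wide: 15       # orientation SD of the wide category (degrees)
sigma_narrow: 3      # orientation SD of the narrow category (degrees)
n_trials: 4000
n_neurons: 12
noise_model: poisson
alpha: 0.75          # planted decoding efficiency of the synthetic subject
subject: regression
seed: 1              # tuning-curve draw
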
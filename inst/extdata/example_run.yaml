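# Example configuration for the CLI `run` subcommand: a small synthetic
# eyes-closed cohort analysed with the regression task.
synthetic:
  n_subjects: 60
  conditions: EC
  duration: 30
  seed: 7
condition: EC
task: regression
threshold: 0.10
n_probes: 100
max_hidden: 2
n_restarts: 4
fraction: 0.70
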
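# Fixture configuration reproducing the full synthetic study design shape:
# ageing genotypes x four tissues x adult days 1,3,5,7,10 (Day 7 dropped for
# neurons), 30 animals per design cell, BafA and rab-7 RNAi arms, default
# colocalization fractions. Mean trajectories fall back to package defaults.
alpha: 0.01
seed: 1
n_animals_per_cell: 30
flux_scenarios: [12, 24, 6]
coloc_fractions: [0.10, 0.75, 0.15]
drop_neuron_day7: true
observe_at: .inf
assumed_flux: 12
perturbation_effects:
  control: [1, 1]
  bafa: [0.33333333333333, 0.5]
  rab7_rnai: [0.2, 1]
output_dir: autoflux-run
log_level: INFO
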
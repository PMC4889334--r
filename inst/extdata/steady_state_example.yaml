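# Example scenario configuration for `run_simulate()` / the ribotrace CLI.
# Scenario names, constructs and kinetics overrides are documented in
# ?scenario_config and ?kinetic_parameters.
scenario: steady_state
construct: kif18b_suntag24
n_mrna: 50
duration_s: 1800
frame_interval_s: 30
noise: [0.2, 0.1]
seed: 1
kinetics:
  k_init: 0.04
  k_elong: 3.5
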
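grid:
- 500
- 500
n_do_init: 200
n_food_init: 100
genome_length: 20000
wgd_rate: 0.4
substitution_rate: 0.0001
move_cost: 70.0
replication_threshold: 20000.0
scenario:
  mode: dynamic
  fraction: 0.85
  period: 60
  pop_trigger: 1000
  fixed_step: 300
max_steps: 1000
population_cap: 2000
sensing_radius: 5
grn_threshold: 1.0
grn_cap: 100.0
decay_range:
- 0.05
- 0.25
stability_window: 10
ed_threshold: 0.3
food_energy_range:
- 10000.0
- 20000.0
food_growth: 300.0
init_energy: 10000.0
offspring_energy: split
bootstrap_tf_count: 12
bootstrap_tf_value: 10.0
selection_free: no
stop_on_class_extinction: yes
stop_at_equalization: no
master_seed: 1
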
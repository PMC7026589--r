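# Example experiment configuration for run_experiment() / the CLI.
# Simulates the ultraviolet repair-trapping landmark conditions.
mode: simulate
seed: 101
out_dir: cometscreen_example_out
control: vehicle
n_wells: 3
comets_per_well: 150
scenarios:
  vehicle:
    agent: vehicle
    dose: 0
    time_h: 1
  vehicle_huarac:
    agent: vehicle
    dose: 0
    time_h: 1
    hu_arac: true
  uv_1h:
    agent: uvc
    dose: 5
    time_h: 1
  uv_1h_huarac:
    agent: uvc
    dose: 5
    time_h: 1
    hu_arac: true
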
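# Example run configuration: the reference evolution protocol on a seeded
# synthetic score landscape (no external docking engine required).
length: 8
start_sequence: AAAAAAAA
ladder: [0.2, 0.4, 0.6]
n_steps: 100
n_runs: 9
seed: 42
backend:
  type: synthetic
  generate:
    length: 8
    noise_sd: 1.0
    control_offset: 4.0
    seed: 42
# Adapter metadata only (forwarded verbatim to external docking engines;
# the synthetic backend ignores it). Center = sulfur atom of Met330 for the
# maltose site of MBP.
sites:
  binding:
    box_center: [0.0, 0.0, 0.0]
    box_size: [25.0, 25.0, 25.0]
    exhaustiveness: 10
    energy_range: 4
    site_label: binding
  control:
    box_center: [0.0, 0.0, 0.0]
    box_size: [25.0, 25.0, 25.0]
    exhaustiveness: 10
    energy_range: 4
    site_label: control
rescore:
  kBT: 0.6
  n_runs: 10
  n_steps: 100
  retain_last: 10
rt: 0.593
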
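# Example run configuration: the bistable archetype pair under the daily
# serial-transfer protocol, with small sweep grids for a quick demo.
backend: ode
seed: 1
out_dir: phfeedback_out
species:
  Lp: {}          # archetype defaults from archetypes.yaml
  Ca: {}
environment:
  b: 5.0
  p0: 5.0
protocol:
  cycle_length: 5.0
  dilution_factor: 100.0
  n_cycles: 8
sweep:
  n_density: 11
  n_fraction: 11
  n_p0: 11
  total_density: 1.0
noise:
  growth_sd: 0.1
  ph_sd: 0.05
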
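# Example run configuration for the gaitfog CLI (`gaitfog run --config ...`).
preset: cowie_pd_off
door: narrow
seed: 7
n_train_passes: 100
n_test_passes: 100
n_profiles: 50
output_dir: results/pd_off_narrow
flags:
  wall_rule: clip
  clamp_switching: false
  orientation: displacement
  backward_rule: tiny_step
  max_steps: 500
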
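# Demo pipeline configuration: a small synthetic two-group cohort
# (8 channels, 10 subjects per group, 60 s -> 30 two-second epochs)
# with a star-topology shift in the upper alpha band for the IA group.
cohort:
  n_per_group: 10
  channel_labels: [FP1, FP2, F3, F4, C3, C4, O1, O2]
  fs: 125
  duration_s: 60
  bands: [alpha2]
  coupling: 0.5
  hub: O1
  artifact_prob: 0.05
  group_effects:
    alpha2:
      star_bias: 0.2
bands: [alpha2]
epoch_len_s: 2
amp_threshold: 150
min_epochs: 20
bonferroni_m: 9
out_dir: mstnet-demo-report
seed: 7
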
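# Demo pipeline configuration: simulate both tissue presets, quantify and
# compare them, run the colony readout, and build signatures from a
# synthetic DE table. Paths are created under out_dir.
seed: 7
out_dir: lineage_fidelity_demo
stages: [tissue, colony, signatures]
tissue:
  presets: [HR, AR]
  n_samples: [5, 5]
  images_per_sample: 3
  metric: r_lep
colony:
  presets: [AR-day2, HR-day2]
  n_cells: 600
signatures:
  n_genes: 2000
  frac_up: 0.05
  frac_down: 0.05
  effect_log2fc: 3
  worked_example: [77, 100, 100, 1000]
age_groups:
  young_max: 35
  old_min: 55
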
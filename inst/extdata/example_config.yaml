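# Example mirassoc pipeline configuration: a fully synthetic study at
# reduced scale. Replace the simulate block with an `inputs:` section of
# TSV paths to run on real tables.
seed: 1
out_dir: mirassoc_run
simulate:
  n_samples: 57
  n_mirs: 100
  n_mrnas: 1000
  n_true_pairs: 30
  db_coverage: 1
  n_decoys: 5000
selection:
  mi_top_pct: 10
  r_bottom_pct: 2.5
predictions:
  targetscan_pct: 15
  diana_pct: 30
go:
  substrings: [epith, mesench, pigment, melan]
  min_size: 5
  max_size: 500
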
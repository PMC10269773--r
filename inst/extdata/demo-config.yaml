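# Demo pipeline configuration: a small paired (+Cfx / control) simulated
# experiment. Any key under these sections overrides the package default
# (see ?default_pipeline_config).
simulate:
  seed: 42
  n_reads: 50000
  genome_length: 200000
  gc_fraction: 0.51
  chi_count: 12
  gcs_count: 6
  ter_chi_distance: [8000, 12000]
align:
  multimappers: first
profile:
  window: 20000
  step: 5000
  pseudocount: 1
chi:
  half_width: 50000
  smoothing: 400
  flank: [35000, 50000]
  drop_window: 2000
  enrichment_span: [0, 5000]
  enrichment_smoothing: 1000
  n_perm: 2000
compose:
  flank: 20
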
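# Demo pipeline configuration: a miniature panel that exercises every
# stage in well under a minute. The seed is mandatory.
seed: 7
panel:
  n_spring: 4
  n_winter: 1
  treatments: [B0, B1]
  replicates_per_condition: 12
  efficient_fraction: 0.4
  noise_cv: 0.15
phenotyping:
  n_accessions: 3
  replicates: 4
cessation:
  n_accessions: 2
  replicates: 3
  seedlings_per_replicate: 5
images:
  n_images: 2
  shape: disk
  size: 30
  canvas_px: 96
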
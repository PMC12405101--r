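# Demo pipeline configuration: a 1.2-km synthetic landscape with a
# reduced reference inventory, default sensors, and the standard district
# model settings. Run with:
#   Rscript inst/scripts/lichenline.R run-all --config inst/extdata/demo_config.yaml --out demo_out
landscape:
  extent_m: [1200, 1200]
  base_pixel_m: 2
  n_lakes: 6
  n_fens: 3
  n_sandpits: 5
buffers_m: [200, 1000]
rescale_pixels_m: [10, 30, 60]
seed: 11
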
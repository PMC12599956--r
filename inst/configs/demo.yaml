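# Demo pipeline: synthetic tissue -> classification -> randomization null
# test. Run with: giantcell pipeline --config demo.yaml
# (paths are relative to the working directory)
seed: 11
outdir: demo_out
stages:
- stage: synth
  n_cells: 160
  width: 128
  height: 128
  tail_fraction: 0.05
  n_stomata: 2
  out: tissue.csv
  table: cells.csv
  outputs:
  - demo_out/tissue.csv
  - demo_out/cells.csv
- stage: classify
  table: demo_out/cells.csv
  threshold_from:
  - demo_out/cells.csv
  percentile: 92
  out: typed.csv
  outputs:
  - demo_out/typed.csv
- stage: stats
  tissue: demo_out/tissue.csv
  table: demo_out/typed.csv
  n_random: 100
  direction: greater
  out: result.json
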
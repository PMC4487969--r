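# Example run configuration for run_report(); `records` is resolved
# relative to the working directory.
records: hut_records.csv
control_arm: untreated
species:
  - "An. funestus"
  - "An. gambiae"
  - "An. arabiensis"
alpha: 0.05
digits: 1
out_dir: results
seed: 1
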
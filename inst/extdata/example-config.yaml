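# Example declarative run configuration (see read_run_config()).
session:
  duration_s: 600
  spindle_rate: 12
  n_tc_units: 12
  n_nrt_units: 12
  n_shanks: 1
detection:
  threshold_sd: 2
  min_cycles: 5
seed: 1
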
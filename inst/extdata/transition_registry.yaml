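# Default transition-parameter registry for the stage II colon cancer
# cohort model: published point estimates for the five parameterized
# transitions. The DIAG-DOC baseline rate (printed only to three decimals,
# as 0.000 with CI (0.000; 0.001)) is stored here at the value calibrated
# against the monthly REC-DOC probability column; see
# calibrate_doc_baseline_rate().
p90dm_by_age:
  "50-54": 0.028
  "55-59": 0.028
  "60-64": 0.032
  "65-69": 0.032
  "70-74": 0.064
  "75-79": 0.073
  "80-84": 0.114
  "85-89": 0.156
  "90-95": 0.333
diag_doc:
  family: gompertz
  shape: 0.010
  rate_or_scale: 0.00022883875817988141
  coefficients:
    "50-54": 0.0
    "55-59": 0.632
    "60-64": 0.591
    "65-69": 1.039
    "70-74": 1.701
    "75-79": 2.159
    "80-84": 2.823
    "85-89": 3.166
    "90-95": 3.315
diag_rec:
  family: gompertz
  shape: -0.016
  rate_or_scale: 0.004
  coefficients:
    GE10: -0.519
    pT4: 1.081
    left: 0.505
rec_death:
  family: loglogistic
  shape: 1.17
  rate_or_scale: 1390.0
  coefficients:
    "50-54": -3.439
    "55-59": -3.766
    "60-64": -4.094
    "65-69": -4.421
    "70-74": -4.749
    "75-79": -5.076
    "80-84": -5.404
    "85-89": -5.731
    "90-95": -6.059
rec_doc_by_age:
  "50-54": 0.000
  "55-59": 0.001
  "60-64": 0.001
  "65-69": 0.001
  "70-74": 0.002
  "75-79": 0.003
  "80-84": 0.004
  "85-89": 0.005
  "90-95": 0.006
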
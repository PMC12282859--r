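n_subjects: 4144.0
seed: ~
covariates:
  age:
    kind: continuous
    mean: 52.1
    sd: 16.12
    lower: 22.0
    upper: 85.0
  sex:
    kind: categorical
    labels:
    - female
    - male
    probs:
    - 0.4994
    - 0.5006
    reference: female
  calcium:
    kind: continuous
    mean: 8.91
    sd: 0.8
    lower: 4.0
    upper: 14.0
  ldl:
    kind: continuous
    mean: 107.4
    sd: 29.9
    lower: 20.0
    upper: 300.0
  esr:
    kind: continuous
    mean: 55.0
    sd: 25.0
    lower: 1.0
    upper: 150.0
  sbp:
    kind: continuous
    mean: 128.0
    sd: 15.0
    lower: 80.0
    upper: 220.0
  dbp:
    kind: continuous
    mean: 75.2
    sd: 10.0
    lower: 40.0
    upper: 130.0
cure:
  link: cloglog
  intercept: -0.337783252599
  coef: ~
latency:
  shape: 1.5
  scale: 4.31909
  coef: ~
  truncation: 11.72
censoring:
  kind: exponential
  rate: 0.17674
study_window_years: 18.0
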
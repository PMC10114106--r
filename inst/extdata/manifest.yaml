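lm:
  file: cohort_lm.csv
  'n': 150.0
  n_continuous: 10
  n_categorical: 5
  n_levels: 3
  rho: 0.2
  beta:
    x1: 0.3
    x2: 0.3
    x3: 0.3
    x4: 0.3
  interaction_beta: {}
  covariate_beta:
    age: 0.2
    sex: 0.2
  intercept: 0.0
  family: lm
  baseline_hazard: 0.1
  censor_horizon: 10.0
  missing_rate: 0.02
  unwanted_rate: 0.02
  unwanted_code: prefer_not_to_answer
  seed: 101
logistic:
  file: cohort_logistic.csv
  'n': 150.0
  n_continuous: 10
  n_categorical: 5
  n_levels: 3
  rho: 0.2
  beta:
    x1: 0.3
    x2: 0.3
    x3: 0.3
    x4: 0.3
  interaction_beta: {}
  covariate_beta:
    age: 0.2
    sex: 0.2
  intercept: -0.8472979
  family: logistic
  baseline_hazard: 0.1
  censor_horizon: 10.0
  missing_rate: 0.02
  unwanted_rate: 0.02
  unwanted_code: prefer_not_to_answer
  seed: 102
cox:
  file: cohort_cox.csv
  'n': 150.0
  n_continuous: 10
  n_categorical: 5
  n_levels: 3
  rho: 0.2
  beta:
    x1: 0.3
    x2: 0.3
    x3: 0.3
    x4: 0.3
  interaction_beta: {}
  covariate_beta:
    age: 0.2
    sex: 0.2
  intercept: 0.0
  family: cox
  baseline_hazard: 0.1
  censor_horizon: 10.0
  missing_rate: 0.02
  unwanted_rate: 0.02
  unwanted_code: prefer_not_to_answer
  seed: 103
lm_interactions:
  file: cohort_lm_interactions.csv
  'n': 150.0
  n_continuous: 10
  n_categorical: 5
  n_levels: 3
  rho: 0.2
  beta:
    x1: 0.3
    x2: 0.3
    x3: 0.3
    x4: 0.3
  interaction_beta:
    x1:x2: 0.3
  covariate_beta:
    age: 0.2
    sex: 0.2
  intercept: 0.0
  family: lm
  baseline_hazard: 0.1
  censor_horizon: 10.0
  missing_rate: 0.02
  unwanted_rate: 0.02
  unwanted_code: prefer_not_to_answer
  seed: 104
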
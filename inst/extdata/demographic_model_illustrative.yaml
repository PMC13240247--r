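# Illustrative (synthetic) disturbance-demography model.
# These are NOT the published national regression coefficients; they have
# the same structure (beta regressions of adult female survival and
# recruitment on range disturbance, mean/precision parameterization) and
# the same qualitative behaviour (both rates decline with anthropogenic
# disturbance). Replace with transcribed published values for real use.
#
# Units: covariates are percentages (0-100); the recruitment linear
# predictor is on the calves-per-100-cows scale.
survival:
  model_id: M4
  link: logit
  intercept: 2.2
  coef_anthro: -0.02
  coef_fire: -0.005
  precision: 60
recruitment:
  model_id: M1
  link: log
  intercept: 3.35
  coef_anthro: -0.011
  coef_fire: -0.003
  precision: 15
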
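tv_kin: 0.116
tv_int_dis: 1.16
tv_slope_dis: -0.0001
tv_emax: 0.36
ratio_edk50_emax: 8.66
kde: 1.0
covariate_effects:
- covariate: severity
  parameter: int_dis
  kind: multiplicative
  theta: 0.62
  reference: ~
- covariate: sex
  parameter: int_dis
  kind: multiplicative
  theta: 0.82
  reference: ~
- covariate: pics
  parameter: int_dis
  kind: multiplicative
  theta: 0.92
  reference: ~
- covariate: height
  parameter: int_dis
  kind: power
  theta: 1.9
  reference: 170.0
- covariate: severity
  parameter: emax
  kind: multiplicative
  theta: 0.94
  reference: ~
- covariate: reversibility
  parameter: emax
  kind: multiplicative
  theta: 1.05
  reference: ~
omega:
  names:
  - int_dis
  - emax
  values:
  - 0.0625
  - 0.0
  - 0.0
  - 0.49
sigma_add: 0.13
sigma_prop: 0.0
hazard:
  form: constant
  beta0: 0.006
  beta1: 0.0
  beta2: -0.88
  shape: 1.0
drug_effect_mode: multiplicative_kin
exposure_parameterisation: a
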
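master_seed: 1
bootstrap_reps: 1000
scenarios:
- label: misconception1_uniform_perfect_n1000
  'n': 1000
  replicates: 5000
  master_seed: 2
  redraw_q: yes
  truth:
    family: uniform
    min: 0.0
    max: 1.0
  perturbation:
    kind: identity
    magnitude: 0.0
    clip_policy: clip_to_unit
- label: misconception1_uniform_noise_n1000
  'n': 1000
  replicates: 5000
  master_seed: 3
  redraw_q: yes
  truth:
    family: uniform
    min: 0.0
    max: 1.0
  perturbation:
    kind: uniform_noise
    magnitude: 0.1
    clip_policy: clip_to_unit
- label: misconception1_nhanes_perfect_n1000
  'n': 1000
  replicates: 5000
  master_seed: 4
  redraw_q: no
  truth:
    family: logistic_model
    beta:
    - 0.5
    - 0.5
    - 0.5
    intercept: -1.5894332
    k: 3
    covariates: std_normal
  perturbation:
    kind: identity
    magnitude: 0.0
    clip_policy: clip_to_unit
- label: misconception2_beta_noise_n1000
  'n': 1000
  replicates: 5000
  master_seed: 5
  redraw_q: yes
  truth:
    family: beta
    shape1: 1.0
    shape2: 3.0
  perturbation:
    kind: uniform_noise
    magnitude: 0.1
    clip_policy: clip_to_unit
- label: misconception2_two_point_perfect_n300
  'n': 300
  replicates: 5000
  master_seed: 6
  redraw_q: yes
  truth:
    family: two_point
    v0: 0.0
    v1: 1.0
    w: 0.5
  perturbation:
    kind: identity
    magnitude: 0.0
    clip_policy: clip_to_unit
- label: misconception3_bias_n300
  'n': 300
  replicates: 5000
  master_seed: 7
  redraw_q: yes
  truth:
    family: uniform
    min: 0.0
    max: 1.0
  perturbation:
    kind: additive_bias
    magnitude: 0.1
    clip_policy: clip_to_unit
- label: misconception3_logit_noise_n300
  'n': 300
  replicates: 5000
  master_seed: 8
  redraw_q: yes
  truth:
    family: uniform
    min: 0.0
    max: 1.0
  perturbation:
    kind: logit_noise
    magnitude: 0.5
    clip_policy: clip_to_unit
- label: misconception4_constant_half_n300
  'n': 300
  replicates: 5000
  master_seed: 9
  redraw_q: yes
  truth:
    family: constant
    value: 0.5
  perturbation:
    kind: identity
    magnitude: 0.0
    clip_policy: clip_to_unit
- label: misconception5_uniform_perfect_n300
  'n': 300
  replicates: 5000
  master_seed: 10
  redraw_q: yes
  truth:
    family: uniform
    min: 0.0
    max: 1.0
  perturbation:
    kind: identity
    magnitude: 0.0
    clip_policy: clip_to_unit
- label: misconception5_beta_perfect_n300
  'n': 300
  replicates: 5000
  master_seed: 11
  redraw_q: yes
  truth:
    family: beta
    shape1: 1.0
    shape2: 3.0
  perturbation:
    kind: identity
    magnitude: 0.0
    clip_policy: clip_to_unit
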
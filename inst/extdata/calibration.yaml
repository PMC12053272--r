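# Trait-to-metric calibration for the virtual-respondent cohort.
# meanlog: log-ms location of the lognormal decision-time component
#   (added to the respondent's base time t0); cost: per-condition log-RT
#   shifts; b: per-condition accuracy offsets (logit); n_options drives
#   guessing accuracy on anticipations.
# Defaults chosen so simulated task means land inside the response-time /
# accuracy / span ranges reported for comparable tasks in the literature.
schema: 1
defaults:
  a: 1.5              # accuracy discrimination per SD of ability
  beta: 0.12          # log-RT decrease per SD of ability
  b_default: 2.8
  t0_range: [150.0, 220.0]
  sigma_range: [0.25, 0.35]
  lapse_range: [0.01, 0.05]
  anticipatory_range: [0.005, 0.02]
  omission_share: 0.1
  kappa_mean: 5.8     # span capacity at ability 0
  kappa_sd: 1.0
  span_gamma: 1.2     # recall-success slope per item of headroom
  high_risk_rate: 0.02
  moderate_risk_rate: 0.1
tasks:
  basic_rt:
    meanlog: 5.04
    n_options: 1
    cost: {}
    b: {target: 4.0}
  span_fwd:
    meanlog: 5.8
    cost: {}
    b: {}
  span_bwd:
    meanlog: 5.9
    cost: {}
    b: {}
  flanker:
    meanlog: 5.51
    n_options: 2
    cost: {incongruent: 0.12}
    b: {congruent: 3.9, incongruent: 3.1}
  cpt_impulsive:
    meanlog: 5.18
    n_options: 2
    cost: {}
    b: {target: 3.7, noresp: 3.1}
  cpt_sustained:
    meanlog: 5.62
    n_options: 2
    cost: {}
    b: {target: 3.7, noresp: 3.1}
  stroop:
    meanlog: 6.18
    n_options: 4
    cost: {incongruent: 0.10}
    b: {congruent: 3.4, incongruent: 2.5}
  boxed:
    meanlog: 6.50
    n_options: 2
    cost: {feature_4: -0.25, feature_12: -0.05, conjunction_4: 0.0, conjunction_12: 0.30}
    b: {feature_4: 3.9, feature_12: 3.5, conjunction_4: 3.3, conjunction_12: 2.8}
  compass:
    meanlog: 5.96
    n_options: 2
    cost: {neutral: 0.0, congruent: -0.05, incongruent: 0.10}
    b: {neutral: 3.5, congruent: 3.7, incongruent: 3.1}
  taskswitch:
    meanlog: 6.43
    n_options: 2
    cost: {stay: -0.10, switch: 0.15}
    b: {stay: 3.5, switch: 2.9}
  tap_trace:
    meanlog: 6.27
    n_options: 2
    cost: {tap_target: -0.15, dual_target: 0.15}
    b: {tap_target: 3.5, tap_noresp: 3.1, dual_target: 3.2, dual_noresp: 2.9}
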
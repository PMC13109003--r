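# Scenario presets for the variance study: factorial rows of
#   near positivity violation x dependence on unmeasured U x rare competing event.
# Shared settings: (pL, pU, theta0..theta3) = (0.1, 0.5, -1, -2, 1, 3).
# The per-row beta (and u-terms of theta) below are documented stand-in values
# chosen so each row satisfies its flags:
#   - "rare" rows keep marginal Pr(D=1) below 10%;
#   - near-violation rows push Pr(D=1 | L=1) close to 1 in BOTH arms
#     (survivor probability ~0.002 in the L=1 stratum), so that the
#     censoring weights explode while the separable-effect weight ratios
#     stay bounded;
#   - U-dependence rows give both event processes nonzero u-coefficients.
# Override this file (scenario_presets(file = ...)) to use other values.
pL: 0.1
pU: 0.5
pA: 0.5
scenarios:
  - name: noviol_noU_rare
    theta: [-1, -2, 1, 3, 0, 0, 0]
    beta: [-2.6, 0.4, 0.4, 0, 0, 0, 0]
    flags: {near_positivity_violation: false, u_dependence: false, rare_competing_event: true}
  - name: noviol_noU_common
    theta: [-1, -2, 1, 3, 0, 0, 0]
    beta: [-1, 0.5, 0.5, 0, 0, 0, 0]
    flags: {near_positivity_violation: false, u_dependence: false, rare_competing_event: false}
  - name: noviol_U_common
    theta: [-1, -2, 1, 3, 1, -0.5, 0.5]
    beta: [-1, 0.5, 0.5, 0, 1, 0.5, -0.5]
    flags: {near_positivity_violation: false, u_dependence: true, rare_competing_event: false}
  - name: nearviol_noU_rare
    theta: [-1, -2, 1, 3, 0, 0, 0]
    beta: [-9, 0.3, 15, 0, 0, 0, 0]
    flags: {near_positivity_violation: true, u_dependence: false, rare_competing_event: true}
  - name: nearviol_noU_common
    theta: [-1, -2, 1, 3, 0, 0, 0]
    beta: [-1, 0.3, 7, 0, 0, 0, 0]
    flags: {near_positivity_violation: true, u_dependence: false, rare_competing_event: false}
  - name: nearviol_U_common
    theta: [-1, -2, 1, 3, 1, -0.5, 0.5]
    beta: [-1, 0.3, 7, 0, 0.5, 0.5, 0.5]
    flags: {near_positivity_violation: true, u_dependence: true, rare_competing_event: false}
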
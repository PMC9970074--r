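# SYNTHETIC informative prior file for the confirmatory competence model.
# These are illustrative stand-in values (not posterior estimates from any
# real dataset) showing the expected layout: per instrument, per coefficient,
# a Gaussian prior mean and sd. Coefficients are named after the predictor
# columns of the confirmatory design (skills 1, 6, 7; activation/instrength/
# outstrength), plus "intercept".
OPTION-12:
  intercept: {mean: 16.0, sd: 5.0}
  activation_skill_1: {mean: 4.0, sd: 6.0}
  activation_skill_6: {mean: 40.0, sd: 25.0}
  activation_skill_7: {mean: 3.0, sd: 10.0}
  instrength_skill_1: {mean: 3.0, sd: 8.0}
  instrength_skill_6: {mean: 2.0, sd: 7.0}
  instrength_skill_7: {mean: 1.0, sd: 6.0}
  outstrength_skill_1: {mean: -7.0, sd: 9.0}
  outstrength_skill_6: {mean: 3.0, sd: 6.0}
  outstrength_skill_7: {mean: -6.0, sd: 5.0}
OPTION-5:
  intercept: {mean: 12.0, sd: 5.0}
  activation_skill_1: {mean: 2.0, sd: 7.0}
  activation_skill_6: {mean: 60.0, sd: 30.0}
  activation_skill_7: {mean: 8.0, sd: 10.0}
  instrength_skill_1: {mean: -3.0, sd: 10.0}
  instrength_skill_6: {mean: 7.0, sd: 8.0}
  instrength_skill_7: {mean: 2.0, sd: 7.0}
  outstrength_skill_1: {mean: -6.0, sd: 13.0}
  outstrength_skill_6: {mean: 0.0, sd: 7.0}
  outstrength_skill_7: {mean: -5.0, sd: 6.0}
4HCS:
  intercept: {mean: 33.0, sd: 5.0}
  activation_skill_1: {mean: 1.5, sd: 5.0}
  activation_skill_6: {mean: 19.0, sd: 16.0}
  activation_skill_7: {mean: 8.0, sd: 8.0}
  instrength_skill_1: {mean: 4.5, sd: 7.0}
  instrength_skill_6: {mean: 1.5, sd: 5.0}
  instrength_skill_7: {mean: -1.5, sd: 5.0}
  outstrength_skill_1: {mean: -5.5, sd: 7.0}
  outstrength_skill_6: {mean: 4.5, sd: 5.0}
  outstrength_skill_7: {mean: -1.5, sd: 4.0}
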
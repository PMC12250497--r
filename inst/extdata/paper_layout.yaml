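# Default replicate-plate scenario: 4 subjects x (8 pooled + 8 independent)
# assays over eight 8-chamber slides, with a graded positional bias profile:
# chamber 1 uniformly dimmed (gain 0.8 in both channels), chambers 2-3
# green-dimmed (carrying the bias into beta values, downward), chambers 7-8
# red-dimmed (beta bias upward), and chamber-8 red bead-level noise
# inflated 1.5x. Channel-asymmetric components are what give chambers
# systematic beta-scale biases; equal-channel dimming cancels in the ratio.
n_subjects: 4
n_pooled_per_subject: 8
n_independent_per_subject: 8
n_probes: 20000
chamber_gain:
  - {chamber: 1, channel: green, value: 0.80}
  - {chamber: 1, channel: red, value: 0.80}
  - {chamber: 2, channel: green, value: 0.78}
  - {chamber: 3, channel: green, value: 0.85}
  - {chamber: 7, channel: red, value: 0.90}
  - {chamber: 8, channel: red, value: 0.82}
chamber_cv_inflation:
  - {chamber: 8, channel: red, value: 1.5}
seed: 1
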
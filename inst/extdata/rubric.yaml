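# Default five-feature clinical priority rubric (0-10 points total).
# Graded features list ascending thresholds and the points awarded
# below / between / at-or-above them. Calibrated reconstruction; see the
# package vignette for how the thresholds were chosen.
n_cases:
  thresholds: [10, 50]
  points: [0, 1, 2]
ror025:
  thresholds: [2, 5]
  points: [0, 1, 2]
mortality:
  thresholds: [0.25, 0.5]
  points: [0, 1, 2]
importance:
  "NA": 0
  "IME": 1
  "DME": 2
evidence:
  "+": 1
  "++": 2
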
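# Default fuzzy-model configuration.
#
# Membership functions are trapezoids (a, b, c, d) forming a partition of
# unity over each universe: pH on the display scale 0-14, cell density
# normalised to [0, 1], per-capita density change on [-1, 1], pH-change
# magnitude on [0, 1].
#
# Growth rules: positive when the current pH label equals the species'
# preferred-pH label, zero for adjacent labels, negative for distant ones;
# high cell density saturates growth (the fuzzy carrying capacity).
# pH-change rules: the more bacteria, the faster the pH moves; direction and
# relative strength are species properties applied outside the rule base.
universes:
  ph: [0.0, 14.0]
  density: [0.0, 1.0]
  change: [-1.0, 1.0]
  magnitude: [-1.0, 1.0]
partitions:
  ph:
    universe: ph
    labels:
      low:    [0.0, 0.0, 4.0, 6.2]
      medium: [4.0, 6.2, 6.2, 8.2]
      high:   [6.2, 8.2, 14.0, 14.0]
  density:
    universe: density
    labels:
      low:    [0.0, 0.0, 0.05, 0.4]
      medium: [0.05, 0.4, 0.4, 0.8]
      high:   [0.4, 0.8, 1.0, 1.0]
  change:
    universe: change
    labels:
      negative: [-1.0, -1.0, -0.7, 0.0]
      zero:     [-0.7, 0.0, 0.0, 0.7]
      positive: [0.0, 0.7, 1.0, 1.0]
  magnitude:
    universe: magnitude
    labels:
      none: [-0.4, 0.0, 0.0, 0.4]
      slow: [0.1, 0.5, 0.5, 0.9]
      fast: [0.5, 0.9, 1.0, 1.0]
rules:
  density_change:
    - {ph: low,    preferred_ph: low,    out: positive}
    - {ph: medium, preferred_ph: medium, out: positive}
    - {ph: high,   preferred_ph: high,   out: positive}
    - {ph: low,    preferred_ph: medium, out: zero}
    - {ph: medium, preferred_ph: low,    out: zero}
    - {ph: medium, preferred_ph: high,   out: zero}
    - {ph: high,   preferred_ph: medium, out: zero}
    - {ph: low,    preferred_ph: high,   out: negative}
    - {ph: high,   preferred_ph: low,    out: negative}
    - {cell_density: high, out: zero}
  ph_change:
    - {cell_density: low,    out: none}
    - {cell_density: medium, out: slow}
    - {cell_density: high,   out: fast}
gains:
  density: 0.18
  ph: 0.7
edge_width: 1.0
defuzz_points: 201
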
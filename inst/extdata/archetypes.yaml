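# Species archetypes for the pH-feedback model.
# Proton scale [0, 2b]; high proton concentration displays as low pH.
# c > 0: acidifier (raises proton concentration); c < 0: alkalizer.
environment:
  b: 5.0
  p0: 5.0
species:
  Lp:            # acid-preferring acidifier (self-serving drive; Allee effect)
    p_pref: 8.0
    sigma: 4.0
    delta: 0.5
    c: 0.1
    d: 1.0
    K: 10.0
  Ca:            # alkali-preferring alkalizer (self-serving drive; Allee effect)
    p_pref: 2.0
    sigma: 4.0
    delta: 0.5
    c: -0.1
    d: 1.0
    K: 10.0
  Pv:            # acid-preferring alkalizer (self-harming; ecological suicide)
    p_pref: 8.0
    sigma: 4.0
    delta: 0.5
    c: -0.1
    d: 1.0
    K: 10.0
  Sm:            # mildly alkali-preferring acidifier (self-harming; suicide)
    p_pref: 3.5
    sigma: 4.0
    delta: 0.5
    c: 0.1
    d: 1.0
    K: 10.0
# Canonical coculture pairs. d_a / d_b override the relative drive strength
# of one partner in that pairing (the murder-suicide diagram needs the
# suicidal alkalizer to out-drive its partner; all other pairs use d = 1).
pairs:
  bistability:       {a: Lp, b: Ca}
  successive_growth: {a: Sm, b: Lp}
  extended_suicide:  {a: Pv, b: Lp, d_a: 2.0}
  stabilization:     {a: Pv, b: Sm}
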
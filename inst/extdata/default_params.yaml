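# Default parameterisation of the sole/plaice mixed-fishery model.
# Units: lengths cm, weights g, densities g/L, rates per day, prices EUR/kg.
# Stage average weights and stage mass ratios are derived from the stage
# lengths and the length-weight rule at load time and validated against
# their printed references; they are not configuration inputs.
resources:
  r: 0.1          # resource regrowth rate (semi-chemostat)
  K_m: 0.3        # non-plaice-exclusive resource maximum, split by omega
  K_p: 1.0        # plaice-exclusive resource maximum (3 x K_m)
  R_h: 0.01       # half-saturation density of the functional response
  omega: 0.0      # resource overlap fraction (scenario setting)
plaice:
  L_J: 1.5        # size at settlement
  L_LJ: 10.0      # size at first catch (80 mm mesh)
  L_A: 27.0       # size at landing / maturation
  lw_a: 0.0089
  lw_b: 3.0353
  I_max_J: 0.069
  I_max_LJ: 0.020
  I_max_A: 0.013
  T: 0.0037       # maintenance rate
  delta: 0.36     # food conversion efficiency
  mu: 0.001       # background mortality (~70 % annual survival)
sole:
  L_J: 0.85
  L_LJ: 12.0
  L_A: 24.0
  lw_a: 0.0091
  lw_b: 3.077
  I_max_J: 0.050
  I_max_LJ: 0.016
  I_max_A: 0.011
  T: 0.0032
  delta: 0.36
  mu: 0.001
fishery:
  plaice:
    f_LJ: 5.0e-5  # tuned so the unit-effort discard fraction is 0.3
    f_A: 0.001272
    price: 1.38
  sole:
    f_LJ: 2.0e-6  # tuned so the unit-effort discard fraction is 0.1
    f_A: 0.001455
    price: 10.06
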
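# Example run configuration: producer-line batch scenario written out in
# full (equivalent to `fixture: lineB-batch` plus a noise and fit block).
# Field names carry the units: radius in cm, nitrate in mg/L, light in
# umol m^-2 s^-1, rates per day.
name: lineB-batch-example
params:
  r_X_max: 0.699     # d^-1
  k_N: 4.41          # mg NO3-/L
  k_I: 15.29         # umol/(m^2 s)
  y_X_N: 7.042       # g DW / g nitrate
  r_p_max: 0.327     # mg product / (g DW d)
  k_p: 1.010         # mg NO3-/L
  k_pd: 0.0801       # L / (g DW d)
optics:
  sigma_X: 0.049     # m^2 / g DW
  radius_cm: 8.75
  incident_light:
    - {from_day: 0, I0: 160}
    - {from_day: 2, I0: 350}
schedule:
  mode: batch
  t_end: 8           # d
  initial: {c_X: 0.1, c_N: 500, c_P: 0, V: 5}
sample_days: [0, 1, 2, 3, 4, 5, 6, 7, 8]
noise:
  cv: {biomass: 0.05, nitrate: 0.05, product: 0.05}
  replicates: 2
  seed: 42
fit:
  free: [r_X_max, k_N, y_X_N, r_p_max, k_p, k_pd]
  bounds:
    r_X_max: [0.0699, 6.99]
    k_N: [0.441, 44.1]
    y_X_N: [0.7042, 70.42]
    r_p_max: [0.0327, 3.27]
    k_p: [0.101, 10.10]
    k_pd: [0.00801, 0.801]
  seed: 17
  scaling: max
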
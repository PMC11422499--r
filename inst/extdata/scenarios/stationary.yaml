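# Synthetic culture scenario: stationary growth phase.  Relative to the
# exponential preset, pigment bands are reduced, detrital and dissolved
# material accumulate, the size distribution coarsens and the carbon to
# chlorophyll ratio rises.
pigment_bands:
  - {center: 440, sigma: 24, amplitude: 0.038}
  - {center: 470, sigma: 18, amplitude: 0.019}
  - {center: 490, sigma: 16, amplitude: 0.014}
  - {center: 545, sigma: 25, amplitude: 0.005}
  - {center: 625, sigma: 12, amplitude: 0.004}
  - {center: 676, sigma: 10, amplitude: 0.024}
a_d400: 0.040
s_d: 0.0125
a_g400: 0.080
s_g: 0.0165
c_p532: 0.95
gamma: 0.7
bb_ratio: 0.013
b_g_flat: 0.0006
bb_ratio_dissolved: 0.5
scatter_frac: 0.12
phase:
  decay: 1.5
  floor: 0.25
psd:
  median_um: 16
  gsd: 2.0
  total_pvc_ul_l: 85
noise:
  acs_sd: 0.001
  counts_sd: 2.0
  lisst_rel_sd: 0.02
  pad_od_sd: 0.002
  spike_prob: 0.03
  spike_mag: 8.0
hydro:
  t_m: 21.5
  s_m: 32.0
tchla: 1.2
tchla_cv: 0.05
poc_umol_l: 40.0
poc_cv: 0.06
pad:
  volume_m3: 5.0e-4
  spot_diameter_mm: 17
  n_replicates: 3
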
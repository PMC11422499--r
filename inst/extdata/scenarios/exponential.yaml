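# Synthetic culture scenario: mid-exponential growth phase.
# Amplitudes are absolute (m^-1) for a culture diluted to near-natural
# cell abundance; pigment bands give a smooth absorption spectrum with
# the familiar blue (Soret) and red chlorophyll peaks plus carotenoid
# shoulders.
pigment_bands:
  - {center: 440, sigma: 24, amplitude: 0.055}
  - {center: 470, sigma: 18, amplitude: 0.025}
  - {center: 490, sigma: 16, amplitude: 0.018}
  - {center: 545, sigma: 25, amplitude: 0.006}
  - {center: 625, sigma: 12, amplitude: 0.006}
  - {center: 676, sigma: 10, amplitude: 0.034}
a_d400: 0.020          # detrital absorption at 400 nm, m^-1
s_d: 0.011             # detrital exponential slope, nm^-1
a_g400: 0.050          # CDOM absorption at 400 nm, m^-1
s_g: 0.0150            # CDOM exponential slope, nm^-1
c_p532: 0.80           # particulate attenuation at 532 nm, m^-1
gamma: 0.9             # attenuation power-law exponent
bb_ratio: 0.010        # particulate backscattering ratio b_bp / b_p
b_g_flat: 0.0005       # residual dissolved/colloidal scattering, m^-1
bb_ratio_dissolved: 0.5
scatter_frac: 0.12     # a-tube uncollected-scattering fraction (epsilon)
phase:
  decay: 1.5           # per-radian decay of the backward phase function
  floor: 0.25          # isotropic floor relative to the decaying term
psd:
  median_um: 12
  gsd: 1.8             # geometric standard deviation
  total_pvc_ul_l: 60
noise:
  acs_sd: 0.001        # m^-1 per time step, inside the +/-0.003 stability band
  counts_sd: 2.0       # raw counts per time step
  lisst_rel_sd: 0.02
  pad_od_sd: 0.002
  spike_prob: 0.03     # bubble bursts, kept well under half the record
  spike_mag: 8.0       # multiplicative burst amplitude
hydro:
  t_m: 21.5
  s_m: 32.0
tchla: 2.0             # mg m^-3
tchla_cv: 0.04
poc_umol_l: 25.0
poc_cv: 0.06
pad:
  volume_m3: 5.0e-4    # 0.5 L filtered
  spot_diameter_mm: 17
  n_replicates: 3
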
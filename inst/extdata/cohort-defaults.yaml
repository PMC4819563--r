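# Default ground truth for the synthetic multi-echo relaxometry cohort.
#
# Stratum parameters reproduce the published summary statistics of an
# adolescent cohort born extremely preterm (22-26 weeks) plus term-born
# controls, imaged with a ten-echo T2-weighted protocol:
#   - stratum sizes: 16 preterm male, 27 preterm female, 10 term male,
#     10 term female (63 subjects after exclusions)
#   - white matter volumes (liters, mean +/- sd): published per stratum
#   - white matter effective single-component T2 targets (ms): published
#     group means; the male stratum means are derived so the published
#     preterm (69.2) and term (67.3) group means are reproduced exactly
#     given the stratum sizes
#   - white matter myelin water fraction means: solved to reproduce the
#     published marginal means (preterm 0.25, term 0.26, male 0.26,
#     female 0.25), which are mutually inconsistent at the third decimal
#   - gray matter / CSF volumes: not published (shown only as figures);
#     realistic values with the same preterm/term contrast are used
#   - first-echo SNR: not published; 150 is the declared default
#
# The free-water fraction mean of white matter is NOT listed here: it is
# calibrated at generation time so that the expected effective
# single-component T2 of the white matter mixture equals wm_t2_target
# (see calibrateCsfFraction()).
echo_times_ms: [13, 16, 20, 25, 30, 40, 50, 85, 100, 150]
basis_t2_ms: [20, 80, 2000]
voxel_dims_mm: [2.5, 2.5, 3.0]
grid_shape: [24, 24, 12]
voxel_scale: auto   # voxel-volume scale factor; auto fits the largest head
snr_first_echo: 150
s0: 1000            # common proton-density amplitude, arbitrary units
seed: 1
strata:
  - group: preterm
    sex: male
    n_subjects: 16
    wm_vol_mean: 0.38
    wm_vol_sd: 0.04
    gm_vol_mean: 0.65
    gm_vol_sd: 0.06
    csf_vol_mean: 0.25
    csf_vol_sd: 0.04
    wm_mwf_mean: 0.255
    wm_mwf_sd: 0.05
    wm_csf_frac_sd: 0.006
    wm_t2_target: 68.7     # derived: consistent with group mean 69.2
    gm_mwf_mean: 0.05
    gm_t2_target: 86
  - group: preterm
    sex: female
    n_subjects: 27
    wm_vol_mean: 0.35
    wm_vol_sd: 0.04
    gm_vol_mean: 0.59
    gm_vol_sd: 0.05
    csf_vol_mean: 0.22
    csf_vol_sd: 0.04
    wm_mwf_mean: 0.247
    wm_mwf_sd: 0.06
    wm_csf_frac_sd: 0.006
    wm_t2_target: 69.5
    gm_mwf_mean: 0.05
    gm_t2_target: 86
  - group: term
    sex: male
    n_subjects: 10
    wm_vol_mean: 0.43
    wm_vol_sd: 0.04
    gm_vol_mean: 0.72
    gm_vol_sd: 0.06
    csf_vol_mean: 0.27
    csf_vol_sd: 0.04
    wm_mwf_mean: 0.268
    wm_mwf_sd: 0.04
    wm_csf_frac_sd: 0.006
    wm_t2_target: 67.8     # derived: consistent with group mean 67.3
    gm_mwf_mean: 0.05
    gm_t2_target: 86
  - group: term
    sex: female
    n_subjects: 10
    wm_vol_mean: 0.37
    wm_vol_sd: 0.03
    gm_vol_mean: 0.63
    gm_vol_sd: 0.05
    csf_vol_mean: 0.24
    csf_vol_sd: 0.04
    wm_mwf_mean: 0.252
    wm_mwf_sd: 0.05
    wm_csf_frac_sd: 0.006
    wm_t2_target: 66.8
    gm_mwf_mean: 0.05
    gm_t2_target: 86
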
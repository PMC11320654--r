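# Student-t error-model parameters for DP4+ scoring, per nucleus and error
# kind, plus the reference shielding (TMS computed at the shift-calculation
# level) used to convert isotropic shieldings to chemical shifts.
#
# These values are CONFIGURATION, not constants of the method. The t
# statistics below are the classic DP4-lineage parameters (sigma_C = 2.306
# ppm, nu_C = 11.38; sigma_H = 0.185 ppm, nu_H = 14.18) applied to both the
# scaled and unscaled channels with zero location. Level-of-theory-specific
# parameter sets - in particular the non-zero unscaled-channel locations and
# the exact TMS reference shieldings for a given functional/basis/solvent
# combination (e.g. mPW1PW91/6-31+G** with or without PCM) - are published
# with the DP4+ method and its applications; edit this file, or supply your
# own with read_dp4_params(path, set = ...), to match the level actually
# used for the GIAO job. The sigma_ref values below are representative TMS
# shieldings at mPW1PW91/6-31+G**-class levels and should likewise be
# replaced by the value computed at your exact level.
#
# Two named sets are provided because continuum-solvent (PCM) and gas-phase
# GIAO jobs call for different statistics; they ship with identical values
# as placeholders for user calibration.
pcm:
  H1:
    scaled:   {mu: 0.0, sigma: 0.185, nu: 14.18}
    unscaled: {mu: 0.0, sigma: 0.185, nu: 14.18}
    sigma_ref: 31.84
  C13:
    scaled:   {mu: 0.0, sigma: 2.306, nu: 11.38}
    unscaled: {mu: 0.0, sigma: 2.306, nu: 11.38}
    sigma_ref: 186.52
gas:
  H1:
    scaled:   {mu: 0.0, sigma: 0.185, nu: 14.18}
    unscaled: {mu: 0.0, sigma: 0.185, nu: 14.18}
    sigma_ref: 31.88
  C13:
    scaled:   {mu: 0.0, sigma: 2.306, nu: 11.38}
    unscaled: {mu: 0.0, sigma: 2.306, nu: 11.38}
    sigma_ref: 189.70
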
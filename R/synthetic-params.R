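## Calibrated response of the 20 pipeline-extracted GLCM features to the
## generator's latent texture parameter (log correlation length), used by the
## fast feature-level cohort mode to emulate the image pipeline's output
## distribution. mu0: mean feature value at width 4 px; slope_lw: change per
## unit log width; noise_sd: per-image replicate SD at fixed width. block/sign
## encode the two-block correlation structure of the per-image noise: block 1
## holds the 11 smoothness-driven features (signed by their direction of
## response), block 2 the remaining 9. Values measured once by regressing
## features extracted by the image pipeline (G = 64, distance 1, 256 x 256
## phantoms, 8 replicates at each of 9 widths log-spaced over 1.5-12 px) on
## log width; see the methods vignette.
.glcm_response_params <- function() {
  tab <- matrix(c(
    ## mu0,        slope_lw,    noise_sd
    1377.59,       22.6349,     8.03387,     # autocorrelation
    3.20549e+06,   173835,      60133.2,     # cluster_prominence
    47.9461,       24.9212,     107.621,     # cluster_shade
    37.5932,       -45.7316,    15.8483,     # contrast
    0.944918,      0.0670015,   0.0232183,   # correlation
    2.3651,        -0.681647,   0.0720601,   # difference_entropy
    16.9828,       -20.2669,    6.852,       # difference_variance
    4.04219,       -2.87418,    0.62909,     # dissimilarity
    0.00158236,    0.000983953, 7.17763e-05, # energy
    6.9368,        -0.703666,   0.0637626,   # entropy
    0.295335,      0.147361,    0.0101751,   # homogeneity
    -0.332006,     -0.169196,   0.0153326,   # info_correlation_1
    0.948719,      0.0618472,   0.021419,    # info_correlation_2
    0.011422,      0.0028185,   0.000773048, # maximum_probability
    0.991387,      0.0102509,   0.00338774,  # moment_normalized_inverse_difference
    0.944387,      0.0361377,   0.00704604,  # normalized_inverse_difference
    64.9668,       -0.00491874, 0.0457773,   # sum_average
    1327.28,       45.4454,     16.0005,     # sum_variance
    4.84019,       -0.00229245, 0.00159766,  # sum_entropy
    341.218,       -0.0715639,  0.296549     # variance
  ), ncol = 3, byrow = TRUE)
  data.frame(
    feature = glcm_feature_names(),
    block = c(2, 2, 2, 1, 1, 1, 1, 1, 2, 1, 1, 1, 1, 2, 1, 1, 2, 2, 2, 2),
    sign = c(1, 1, 1, -1, 1, -1, -1, -1, 1, -1, 1, -1, 1, 1, 1, 1, 1, 1, 1, 1),
    mu0 = tab[, 1], slope_lw = tab[, 2], noise_sd = tab[, 3])
}
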
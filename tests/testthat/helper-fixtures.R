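# Shared fixtures, all built in code at test time.

# A small study-shaped synthetic config (three strata, scaled down).
small_config <- function(seed = 42L, delta = c(weidner = 0, elovl2 = 0,
                                               fhl2 = 0),
                         n_scale = 1, ...) {
  st <- default_strata()
  st$breast_female$n_cases <- as.integer(30 * n_scale)
  st$breast_female$n_controls <- as.integer(30 * n_scale)
  st$crc_male$n_cases <- as.integer(22 * n_scale)
  st$crc_male$n_controls <- as.integer(20 * n_scale)
  st$crc_female$n_cases <- as.integer(16 * n_scale)
  st$crc_female$n_controls <- as.integer(16 * n_scale)
  synthetic_config(strata = st, delta = delta, seed = seed, ...)
}

# One stratum only, handy for focused tests.
one_stratum_config <- function(n_cases, n_controls, seed = 1L,
                               delta = c(weidner = 0, elovl2 = 0, fhl2 = 0),
                               outcome = "breast", sex = "female",
                               label = "breast_female", ...) {
  synthetic_config(strata = list(list(
    label = label, outcome = outcome, sex = sex,
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    dx_mean = 3.84, dx_sd = 2.87)),
    delta = delta, seed = seed, ...)
}

# Hand-rolled metadata table emulating the study layout.
toy_metadata <- function() {
  data.frame(
    sample_id = sprintf("s%02d", 1:12),
    sex = c(rep("female", 8), rep("male", 4)),
    age_at_recruitment = c(45, 50, 55, 60, 44, 51, 56, 61, 48, 52, 57, 59),
    outcome = c("breast", "breast", "control", "control",
                "CRC", "control", "other", "control",
                "CRC", "CRC", "control", "control"),
    time_to_diagnosis = c(2.7, 4.1, NA, NA, 5.0, NA, 1.2, NA, 3.3, 6.1,
                          NA, NA),
    stringsAsFactors = FALSE)
}

tiny_beta <- function() {
  beta_matrix(matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), nrow = 2,
                     dimnames = list(c("cgA", "cgB"),
                                     c("s1", "s2", "s3"))))
}
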
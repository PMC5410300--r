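test_that("Mann-Whitney exact mode matches enumeration and wilcox.test", {
  got <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$p_value, 0.1)   # 2 of the C(6,3)=20 labelings as extreme
  expect_equal(got$method, "exact")
  expect_equal(got$statistic, 0)

  # oracle: brute-force enumeration over labelings, written independently
  enum_p <- function(x, y) {
    pooled <- c(x, y); n <- length(pooled); nx <- length(x)
    obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
    mu <- nx * length(y) / 2
    labelings <- utils::combn(n, nx, simplify = FALSE)
    us <- vapply(labelings, function(idx) {
      sum(rank(pooled)[idx]) - nx * (nx + 1) / 2
    }, numeric(1))
    mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
  }
  set.seed(17)
  for (i in 1:30) {
    nx <- sample(1:5, 1); ny <- sample(1:5, 1)
    vals <- sample(1000, nx + ny)  # distinct -> no ties
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    got <- mann_whitney_test(x, y)
    expect_equal(got$p_value, enum_p(x, y))
    expect_equal(got$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("Mann-Whitney handles ties, identity, and symmetry", {
  x <- c(1, 2, 2, 3)
  expect_equal(mann_whitney_test(x, x)$p_value, 1)
  set.seed(23)
  for (i in 1:20) {
    x <- round(rnorm(sample(3:30, 1)), 1)
    y <- round(rnorm(sample(3:30, 1), 0.3), 1)
    a <- mann_whitney_test(x, y); b <- mann_whitney_test(y, x)
    expect_equal(a$p_value, b$p_value)
    expect_equal(b$statistic, length(x) * length(y) - a$statistic)
  }
  # large-sample approximation agrees with wilcox.test's corrected normal
  set.seed(29)
  x <- rnorm(40); y <- rnorm(35, 0.4)
  expect_equal(mann_whitney_test(x, y)$p_value,
               stats::wilcox.test(x, y, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-10)
  expect_error(mann_whitney_test(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney type-I error is calibrated at the null", {
  set.seed(37)
  rej <- mean(replicate(1000, {
    mann_whitney_test(rnorm(30), rnorm(30))$p_value < 0.05
  }))
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(rej, ci[1]); expect_lt(rej, ci[2])
})

test_that("stratify emits the study's strata and excludes 'other' cancers", {
  strata <- stratify(toy_metadata())
  expect_setequal(names(strata), c("breast_female", "crc_male",
                                   "crc_female"))
  expect_false("s07" %in% unlist(lapply(strata, function(s)
    c(s$case_ids, s$control_pool))))  # outcome "other": nowhere
  expect_setequal(strata$crc_male$case_ids, c("s09", "s10"))
  expect_setequal(strata$crc_male$control_pool, c("s11", "s12"))

  fem <- toy_metadata()[toy_metadata()$sex == "female", ]
  expect_warning(s2 <- stratify(fem), "crc_male has no cases")
  expect_false("crc_male" %in% names(s2))
})

test_that("matched control selection honors size, tolerance, and seed", {
  set.seed(51)
  n_case <- 20
  meta <- data.frame(
    sample_id = sprintf("m%03d", 1:120),
    sex = "female",
    age_at_recruitment = c(runif(n_case, 45, 60), runif(100, 35, 64)),
    outcome = c(rep("breast", n_case), rep("control", 100)),
    time_to_diagnosis = c(runif(n_case, 1, 8), rep(NA, 100)))
  cases <- meta$sample_id[1:n_case]
  pool <- meta$sample_id[-(1:n_case)]
  sel <- select_matched_controls(cases, pool, meta, seed = 7L)
  expect_length(sel$ids, n_case)
  expect_length(intersect(sel$ids, cases), 0)
  expect_lte(sel$diagnostics$mean_age_gap, 0.5)
  expect_gt(sel$diagnostics$age_wilcox_p, 0)
  # reproducible under the same seed, valid under others
  sel2 <- select_matched_controls(cases, pool, meta, seed = 7L)
  expect_identical(sel$ids, sel2$ids)
  sel3 <- select_matched_controls(cases, pool, meta, seed = 8L)
  expect_lte(sel3$diagnostics$mean_age_gap, 0.5)

  # pool that is an exact age-copy of the cases, same size: returned whole
  meta_copy <- meta[1:(2 * n_case), ]
  meta_copy$sample_id[(n_case + 1):(2 * n_case)] <- sprintf("c%03d", 1:n_case)
  meta_copy$age_at_recruitment[(n_case + 1):(2 * n_case)] <-
    meta_copy$age_at_recruitment[1:n_case]
  meta_copy$outcome[(n_case + 1):(2 * n_case)] <- "control"
  meta_copy$time_to_diagnosis[(n_case + 1):(2 * n_case)] <- NA
  sel4 <- select_matched_controls(meta_copy$sample_id[1:n_case],
                                  meta_copy$sample_id[-(1:n_case)],
                                  meta_copy, seed = 1L)
  expect_setequal(sel4$ids, meta_copy$sample_id[-(1:n_case)])
  expect_equal(sel4$diagnostics$mean_age_gap, 0)
  expect_gt(sel4$diagnostics$age_wilcox_p, 0.99)

  # shifted pool: no draw can satisfy the tolerance
  meta_shift <- meta
  meta_shift$age_at_recruitment[-(1:n_case)] <-
    pmin(meta_shift$age_at_recruitment[-(1:n_case)] + 20, 110)
  expect_error(select_matched_controls(cases, pool, meta_shift, seed = 1L),
               "tolerance")
  expect_error(select_matched_controls(cases, pool[1:5], meta, seed = 1L),
               "smaller than")
})

test_that("build_strata uses the whole pool when it cannot out-size the cases", {
  co <- generate_cohort(small_config(seed = 61L))
  # the per-sex control pool has finite-population mean-age granularity at
  # this scale, so give the matcher a looser tolerance than the default
  expect_message(
    strata <- suppressWarnings(build_strata(co$meta, seed = 3L, tol = 2)),
    "crc_male.*using full pool unmatched")
  expect_equal(length(strata$crc_male$matched_control_ids), 20)
  expect_equal(length(strata$crc_male$case_ids), 22)
  expect_equal(strata$crc_male$diagnostics$n_draws, 0L)
  # female strata draw from the shared 46-strong female control pool
  expect_length(strata$breast_female$matched_control_ids, 30)
  expect_lte(strata$breast_female$diagnostics$mean_age_gap, 2)
  expect_true(all(strata$breast_female$matched_control_ids %in%
                    co$meta$sample_id[co$meta$outcome == "control" &
                                        co$meta$sex == "female"]))
})

test_that("compare_stratum recovers an injected shift and degenerates cleanly", {
  co <- generate_cohort(one_stratum_config(80, 160, seed = 71L,
                                           delta = c(elovl2 = 0.9)))
  strata <- suppressWarnings(build_strata(co$meta, seed = 5L))
  st <- strata$breast_female
  acc <- accel_pipeline(subset_cohort(co, c(st$case_ids,
                                            st$matched_control_ids)),
                        control_ids = st$matched_control_ids)
  cmp <- compare_stratum(acc, st)
  expect_equal(nrow(cmp), 6)  # 3 clocks x 2 measures
  row <- cmp[cmp$clock == "elovl2" & cmp$measure == "age_accel", ]
  se <- sqrt(3^2 / 80 + 3^2 / 80)  # age_noise_sd = 3 in both groups
  expect_lt(abs(row$mean_diff - 0.9), 2 * se)
  expect_equal(row$n_case, 80); expect_equal(row$n_control, 80)
  # p consistent with means' sign
  expect_equal(sign(row$mean_diff),
               sign(row$mean_case - row$mean_control))

  # one-sample-per-group stratum: exact test over two labelings -> p = 1
  tiny <- list(label = "breast_female",
               case_ids = st$case_ids[1],
               matched_control_ids = st$matched_control_ids[1])
  cmp1 <- compare_stratum(acc, tiny)
  expect_true(all(cmp1$p_value == 1))
})
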
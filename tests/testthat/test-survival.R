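recs <- function(time, event, group = rep(1L, length(time))) {
  data.frame(sample_id = paste0("s", seq_along(time)), time = time,
             event = event, group = group)
}

test_that("group assignment follows the sign rule with >= 0 as accelerated", {
  expect_equal(unname(assign_groups(c(0.5, -0.5, 0))), c(1L, -1L, 1L))
  expect_error(assign_groups(c(1, NA)), "non-finite")
  # OLS-centered control residuals split near half and half
  co <- generate_cohort(one_stratum_config(0, 400, seed = 81L))
  acc <- accel_pipeline(co)
  g <- assign_groups(acc$table$age_accel[acc$table$clock == "elovl2"])
  expect_gt(mean(g == 1L), 0.4); expect_lt(mean(g == 1L), 0.6)
})

test_that("censoring rule and record construction match the design", {
  expect_equal(derive_censor_time(), 14.5)
  expect_equal(derive_censor_time(2010, 1993, 1998), 2010 - 1995.5)
  meta <- data.frame(
    sample_id = c("a", "b"), sex = "female",
    age_at_recruitment = c(50, 52),
    outcome = c("control", "breast"),
    time_to_diagnosis = c(NA, 2.69))
  out <- build_survival_records(meta, c(a = 1L, b = -1L))
  expect_equal(out$time, c(14.5, 2.69))
  expect_equal(out$event, c(0L, 1L))
  expect_equal(out$group, c(1L, -1L))
  expect_error(build_survival_records(meta, c(a = 1L)), "no group")
  meta_bad <- meta; meta_bad$time_to_diagnosis[2] <- NA
  expect_error(build_survival_records(meta_bad, c(a = 1L, b = 1L)),
               "lacks a time_to_diagnosis")
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km$surv, c(0.5, 0))
  expect_equal(km_survival_at(km, c(0.5, 1, 1.5, 2)), c(1, 0.5, 0.5, 0))
  # all censored: constant 1
  km0 <- km_estimate(c(3, 5, 7), c(0, 0, 0))
  expect_equal(nrow(km0), 0)
  expect_equal(km_survival_at(km0, c(1, 10)), c(1, 1))
  # event at 1, censored at 1.5, event at 3: S(1)=2/3, S(3)=0
  km1 <- km_estimate(c(1, 1.5, 3), c(1, 0, 1))
  expect_equal(km1$surv, c(2 / 3, 0))
  expect_equal(km1$n_risk, c(3L, 1L))
})

test_that("Kaplan-Meier agrees with survival::survfit on exhaustive small designs", {
  skip_if_not_installed("survival")
  # all event/censor patterns for n <= 6 over a time grid with ties
  for (n in 2:6) {
    times <- c(1, 1, 2, 3, 3, 4)[seq_len(n)]
    for (mask in 0:(2^n - 1)) {
      event <- as.integer(intToBits(mask)[seq_len(n)])
      km <- km_estimate(times, event)
      sf <- survival::survfit(survival::Surv(times, event) ~ 1)
      if (sum(event) == 0) {
        expect_equal(nrow(km), 0)
        next
      }
      at_events <- summary(sf, times = km$time)
      expect_equal(km$surv, at_events$surv, tolerance = 1e-12)
      expect_equal(km$n_risk, at_events$n.risk)
    }
  }
})

test_that("log-rank test: symmetry, invariance, and textbook value", {
  a <- recs(c(1, 3), c(1, 1)); b <- recs(c(2, 4), c(1, 1))
  lr <- logrank_test(a, b)
  # hand computation over the 4 event times (O/E for group A):
  # t=1: d1=1 E=2/4 V=1/4; t=2: d1=0 E=1/3 V=2/9;
  # t=3: d1=1 E=1/2 V=1/4; t=4: d1=0 E=0 V=0 (risk set of 1)
  # O-E = 2 - 4/3 = 2/3; V = 13/18; chisq = (2/3)^2 / (13/18) = 8/13
  expect_equal(lr$chisq, 8 / 13, tolerance = 1e-12)
  swap <- logrank_test(b, a)
  expect_equal(swap$chisq, lr$chisq)
  expect_equal(swap$p_value, lr$p_value)
  # identical record multisets: statistic 0, p = 1
  same <- logrank_test(a, a)
  expect_equal(same$chisq, 0)
  expect_equal(same$p_value, 1)
  # invariant under strictly monotone time transformations
  tr <- function(df) { df$time <- exp(df$time); df }
  expect_equal(logrank_test(tr(a), tr(b))$chisq, lr$chisq)
  # undefined cases error, never report p = 1
  expect_error(logrank_test(recs(c(5, 5), c(0, 0)), recs(5, 0)),
               "no events")
  expect_error(logrank_test(a, a[0, , drop = FALSE]), "non-empty")
})

test_that("log-rank chisq matches survival::survdiff on random cohorts", {
  skip_if_not_installed("survival")
  set.seed(91)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    time <- round(rexp(n, 0.1) + 0.1, 2)
    event <- rbinom(n, 1, 0.7)
    grp <- rbinom(n, 1, 0.5)
    if (length(unique(grp)) < 2 || sum(event) == 0) next
    mine <- try(logrank_test(recs(time[grp == 0], event[grp == 0]),
                             recs(time[grp == 1], event[grp == 1])),
                silent = TRUE)
    if (inherits(mine, "try-error")) next
    ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(mine$chisq, unname(ref$chisq), tolerance = 1e-10)
  }
})

test_that("survival_suite produces the summary-table shape", {
  co <- generate_cohort(small_config(seed = 101L,
                                     delta = c(fhl2 = 2.0)))
  suppressMessages(strata <- build_strata(co$meta, seed = 3L))
  accel_by_stratum <- lapply(strata, function(st)
    accel_pipeline(subset_cohort(co, c(st$case_ids,
                                       st$matched_control_ids)),
                   control_ids = st$matched_control_ids))
  out <- survival_suite(accel_by_stratum, co$meta, strata)
  expect_equal(sort(rownames(out$p_matrix)),
               sort(c("breast_female", "crc_male", "crc_female")))
  expect_equal(ncol(out$p_matrix), 6)  # 3 clocks x 2 measures
  expect_true(all(out$p_matrix > 0 & out$p_matrix <= 1))
  expect_true(all(out$long$n_accel + out$long$n_decel ==
                    rep(vapply(strata[out$long$stratum], function(st)
                      length(st$case_ids) + length(st$matched_control_ids),
                      numeric(1)))))
})

test_that("strong acceleration drives worse event-free survival", {
  hits <- 0; n_seeds <- 10
  for (i in seq_len(n_seeds)) {
    co <- generate_cohort(one_stratum_config(100, 100, seed = 200L + i,
                                             delta = c(fhl2 = 5)))
    strata <- suppressWarnings(build_strata(co$meta, seed = 1L))
    st <- strata$breast_female
    acc <- accel_pipeline(subset_cohort(co, c(st$case_ids,
                                              st$matched_control_ids)),
                          control_ids = st$matched_control_ids)
    out <- survival_suite(list(breast_female = acc), co$meta, strata,
                          measures = "age_accel")
    if (out$p_matrix["breast_female", "fhl2_age_accel"] < 0.05) {
      # accelerated group must be the one with more events
      rec <- out$records[["breast_female.fhl2.age_accel"]]
      expect_gt(mean(rec$event[rec$group == 1L]),
                mean(rec$event[rec$group == -1L]))
      hits <- hits + 1
    }
  }
  expect_gte(hits, 0.7 * n_seeds)
})
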
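zero_beta <- function(probes, n = 1L, value = 0) {
  beta_matrix(matrix(value, length(probes), n,
                     dimnames = list(probes, paste0("s", seq_len(n)))))
}

test_that("built-in clocks reproduce their published coefficients", {
  cl <- builtin_clocks()
  expect_named(cl, c("weidner", "elovl2", "fhl2"))
  # intercepts at zero methylation
  expect_equal(unname(evaluate_clock(cl$weidner,
                                     zero_beta(required_probes(cl$weidner)))),
               38.0)
  expect_equal(unname(evaluate_clock(cl$elovl2, zero_beta("cg16867657"))),
               -42.35)
  expect_equal(unname(evaluate_clock(cl$fhl2, zero_beta("cg06639320"))),
               -30.12)
  # hand arithmetic: 158.81 * 0.6 - 42.35; 38 - 26.4 - 23.7 + 164.7
  expect_equal(unname(evaluate_clock(cl$elovl2,
                                     zero_beta("cg16867657", value = 0.6))),
               52.936)
  expect_equal(unname(evaluate_clock(cl$weidner,
                                     zero_beta(required_probes(cl$weidner),
                                               value = 1))),
               152.6)
})

test_that("evaluate_clock matches an explicit dot-product oracle", {
  set.seed(11)
  for (cl in builtin_clocks()) {
    probes <- required_probes(cl)
    b <- beta_matrix(matrix(runif(length(probes) * 25), length(probes), 25,
                            dimnames = list(probes, paste0("s", 1:25))))
    got <- evaluate_clock(cl, b)
    # independent oracle: explicit per-sample loop
    want <- vapply(seq_len(25), function(j) {
      acc <- cl$intercept
      for (p in probes) acc <- acc + cl$weights[[p]] * b[p, j]
      acc
    }, numeric(1))
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("identity clocks are linear and monotone in each probe", {
  cl <- builtin_clocks()$weidner
  probes <- required_probes(cl)
  set.seed(3)
  for (i in 1:10) {
    b1 <- runif(3); b2 <- runif(3)
    mk <- function(v) beta_matrix(matrix(v, 3, 1,
                                         dimnames = list(probes, "s")))
    mid <- evaluate_clock(cl, mk((b1 + b2) / 2))
    expect_equal(unname(mid),
                 mean(c(evaluate_clock(cl, mk(b1)),
                        evaluate_clock(cl, mk(b2)))), tolerance = 1e-10)
  }
  base <- evaluate_clock(cl, zero_beta(probes, value = 0.5))
  for (p in probes) {
    v <- rep(0.5, 3); names(v) <- probes
    v[p] <- 0.6
    up <- evaluate_clock(cl, beta_matrix(matrix(v, 3, 1,
                                                dimnames = list(probes, "s"))))
    if (cl$weights[[p]] > 0) expect_gt(up, base) else expect_lt(up, base)
  }
})

test_that("missing probes and missing values fail loudly; imputation is opt-in", {
  cl <- builtin_clocks()$weidner
  expect_error(evaluate_clock(cl, zero_beta(c("cg02228185", "cg25809905"))),
               "cg17861230")
  b <- zero_beta(required_probes(cl), n = 3, value = 0.4)
  b["cg25809905", "s2"] <- NA
  expect_error(evaluate_clock(cl, b), "sample 's2'")
  # mean imputation: probe mean over s1, s3 is 0.4, so all samples agree
  imp <- evaluate_clock(cl, b, impute = TRUE)
  expect_equal(unname(imp[2]), unname(imp[1]))
})

test_that("coefficient files load, validate, and reproduce the registry", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("probe_id,coefficient",
               "(Intercept),38.0",
               "cg02228185,-26.4",
               "cg25809905,-23.7",
               "cg17861230,164.7"), path)
  mod <- load_clock_coefficients(path, "weidner_file")
  set.seed(4)
  b <- zero_beta(required_probes(mod), n = 10, value = 0)
  b[] <- runif(length(b))
  expect_equal(unname(evaluate_clock(mod, b)),
               unname(evaluate_clock(builtin_clocks()$weidner, b)))

  two_int <- withr::local_tempfile(
    lines = c("probe_id,coefficient", "(Intercept),1", "(Intercept),2",
              "cg1,0.5"))
  expect_error(load_clock_coefficients(two_int, "x"), "exactly one")
  dup <- withr::local_tempfile(
    lines = c("probe_id,coefficient", "(Intercept),1", "cg1,0.5", "cg1,0.2"))
  expect_error(load_clock_coefficients(dup, "x"), "duplicated probe 'cg1'")
})

test_that("a synthetic 353-probe coefficient file yields a transformed clock", {
  # synthetic stand-in for a Horvath-style table (not the published one)
  set.seed(8)
  probes <- sprintf("cg%08d", sample(1e7, 353))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("probe_id,coefficient",
               paste0("(Intercept),", 0.7),
               paste(probes, round(rnorm(353, 0, 0.05), 6), sep = ",")),
             path)
  mod <- load_clock_coefficients(path, "horvath_like",
                                 transform = "horvath_log_linear")
  expect_length(required_probes(mod), 353)
  b <- beta_matrix(matrix(0.5, 353, 2, dimnames = list(probes, c("a", "b"))))
  ages <- evaluate_clock(mod, b)
  lin <- mod$intercept + sum(mod$weights * 0.5)
  expect_equal(unname(ages), rep(horvath_inverse_transform(lin), 2))
})

test_that("log-linear age calibration is the exact two-branch inverse", {
  expect_equal(horvath_inverse_transform(0), 20)
  expect_equal(horvath_inverse_transform(1), 41)
  expect_equal(horvath_inverse_transform(-log(21)), 0)
  x <- seq(-5, 5, length.out = 201)
  expect_equal(horvath_transform(horvath_inverse_transform(x)), x,
               tolerance = 1e-12)
  ages <- seq(0, 100, by = 0.5)
  expect_equal(horvath_inverse_transform(horvath_transform(ages)), ages,
               tolerance = 1e-12)
  # continuous and increasing across the knot, adult_age configurable
  expect_equal(horvath_inverse_transform(1e-12, adult_age = 30),
               30, tolerance = 1e-9)
  expect_true(all(diff(horvath_inverse_transform(x)) > 0))
})
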
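#' @title Control-anchored epigenetic age acceleration
#' @description
#' Age acceleration is defined against the cancer-free controls: DNAm age
#' is regressed on chronological age using controls only (ordinary least
#' squares), and every subject's residual from that fit — observed minus
#' control-expected DNAm age at their chronological age — is their
#' acceleration in years. "Age Accel" uses chronological age alone;
#' "IEAA" (intrinsic epigenetic age acceleration) additionally adjusts
#' for the seven estimated blood cell count covariates, removing
#' leukocyte-composition effects. Positive residual = epigenetically
#' older than a control of the same age (and cell composition).
#' @name epiclock-acceleration
NULL

# Build the regression design matrix shared by fitting and prediction.
accel_design <- function(chron_age, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, chron_age = as.numeric(chron_age))
  if (!is.null(covariates)) {
    covariates <- validate_cell_counts(covariates)
    X <- cbind(X, as.matrix(covariates[blood_cell_types()]))
  }
  X
}

#' Fit the control-only regression anchoring age acceleration
#'
#' Ordinary least squares of DNAm age on chronological age, restricted to
#' the control samples (`control_mask`). When `covariates` is supplied the
#' seven blood cell abundances enter as additional regressors (the IEAA
#' model). Cases never influence the fit, so their residuals measure
#' deviation from the control aging trajectory.
#'
#' Zero-variance covariate columns carry no information and are dropped
#' from the design with a warning (their coefficient is not identifiable
#' alongside the intercept; the residuals are unchanged by the drop).
#' Genuinely collinear designs — e.g. cell fractions that sum to exactly 1
#' across types — are rejected by a condition-number check rather than
#' silently repaired.
#'
#' @param dnam_age numeric vector, DNAm age per sample (years).
#' @param chron_age numeric vector, chronological age per sample (years).
#' @param control_mask logical vector, `TRUE` for the fitting controls.
#' @param covariates optional cell count data.frame aligned with the
#'   samples (rows in the same order as `dnam_age`).
#' @param condition_threshold reject designs whose 2-norm condition
#'   number exceeds this (default `1e8`).
#' @return object of class `control_fit`: coefficients, term names,
#'   `n_controls`, `adjusted` flag, residual sd among controls.
#' @export
fit_control_model <- function(dnam_age, chron_age, control_mask,
                              covariates = NULL,
                              condition_threshold = 1e8) {
  n <- length(dnam_age)
  stopifnot(length(chron_age) == n, length(control_mask) == n,
            is.logical(control_mask))
  if (any(!is.finite(chron_age)))
    abort_validation("non-finite chronological age")
  adjusted <- !is.null(covariates)
  n_ctrl <- sum(control_mask)
  min_n <- if (adjusted) 10L else 3L
  if (n_ctrl < min_n)
    abort_validation("too few controls for %s fit: %d (need >= %d)",
                     if (adjusted) "covariate-adjusted" else "unadjusted",
                     n_ctrl, min_n)
  X <- accel_design(chron_age, covariates)
  dropped <- character(0)
  if (adjusted) {
    ctrl_block <- X[control_mask, -(1:2), drop = FALSE]
    zero_var <- apply(ctrl_block, 2L, function(v) stats::var(v) == 0)
    if (any(zero_var)) {
      dropped <- colnames(ctrl_block)[zero_var]
      warning(sprintf("dropping zero-variance covariate(s): %s",
                      paste(dropped, collapse = ", ")), call. = FALSE)
      X <- X[, !(colnames(X) %in% dropped), drop = FALSE]
    }
  }
  Xc <- X[control_mask, , drop = FALSE]
  y <- dnam_age[control_mask]
  if (any(!is.finite(y)))
    abort_validation("non-finite DNAm age among controls")
  if (n_ctrl <= ncol(Xc))
    abort_validation("need more controls (%d) than coefficients (%d)",
                     n_ctrl, ncol(Xc))
  if (qr(Xc)$rank < ncol(Xc))
    abort_validation("rank-deficient control design (constant regressor?)")
  if (kappa(Xc, exact = TRUE) > condition_threshold)
    abort_validation(
      "ill-conditioned control design (condition number > %g); collinear covariates?",
      condition_threshold)
  fit <- stats::lm.fit(Xc, y)
  res <- fit$residuals
  structure(list(coefficients = fit$coefficients,
                 terms = colnames(Xc),
                 dropped_covariates = dropped,
                 adjusted = adjusted,
                 n_controls = n_ctrl,
                 sigma = sqrt(sum(res^2) / max(1L, n_ctrl - ncol(Xc)))),
            class = "control_fit")
}

#' @export
print.control_fit <- function(x, ...) {
  cat(sprintf("<control_fit> %s, %d controls, sigma %.3f\n",
              if (x$adjusted) "IEAA (cell-adjusted)" else "Age Accel",
              x$n_controls, x$sigma))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Residual age acceleration against a control-anchored fit
#'
#' `residual = DNAmAge - predicted DNAmAge`, computed for every sample
#' (cases and controls alike) from the control-only fit. By OLS the mean
#' residual over the fitting controls is zero, so a positive value means
#' epigenetically older than the control expectation.
#'
#' @param fit a `control_fit` from [fit_control_model()].
#' @param dnam_age,chron_age numeric vectors for the samples to score.
#' @param covariates cell counts for the same samples; required when the
#'   fit is adjusted, must be complete for every sample scored.
#' @return numeric residual vector (years).
#' @export
compute_acceleration <- function(fit, dnam_age, chron_age,
                                 covariates = NULL) {
  stopifnot(inherits(fit, "control_fit"))
  if (fit$adjusted && is.null(covariates))
    abort_validation("fit is cell-adjusted but no covariates supplied")
  X <- accel_design(chron_age, if (fit$adjusted) covariates else NULL)
  X <- X[, fit$terms, drop = FALSE]
  if (anyNA(X)) {
    bad <- which(rowSums(is.na(X)) > 0)[1L]
    nm <- if (!is.null(covariates)) covariates$sample_id[bad] else bad
    abort_validation("missing covariate value for sample '%s'", nm)
  }
  as.numeric(dnam_age - X %*% fit$coefficients)
}

#' Age Accel and IEAA for every sample and clock
#'
#' Runs each clock, fits the unadjusted and cell-adjusted control models
#' on the designated controls, and scores every sample against both.
#'
#' @param cohort a `methyl_cohort` (from [align_cohort()] or
#'   [generate_cohort()]).
#' @param clocks named list of `clock_model`s.
#' @param control_ids sample ids to anchor the fits on; defaults to all
#'   samples with outcome `"control"`. In stratified analyses pass the
#'   stratum's matched controls so residual centering holds within the
#'   comparison.
#' @param impute passed to [evaluate_clock()].
#' @return object of class `accel_result`: `$table` (long data.frame
#'   `sample_id, clock, dnam_age, age_accel, ieaa`), `$fits` (per clock, the
#'   two `control_fit`s), `$ages` (the wide DNAm-age table).
#' @export
accel_pipeline <- function(cohort, clocks = builtin_clocks(),
                           control_ids = NULL, impute = FALSE) {
  stopifnot(inherits(cohort, "methyl_cohort"))
  if (!length(clocks)) abort_validation("no clocks supplied")
  meta <- cohort$meta
  if (is.null(control_ids)) {
    control_mask <- meta$outcome == "control"
  } else {
    unknown <- setdiff(control_ids, meta$sample_id)
    if (length(unknown))
      abort_validation("control id(s) not in cohort: %s",
                       paste(utils::head(unknown, 3L), collapse = ", "))
    control_mask <- meta$sample_id %in% control_ids
  }
  has_cells <- !is.null(cohort$cells)
  if (!has_cells)
    warning("no cell counts in cohort: IEAA columns will be NA",
            call. = FALSE)
  ages <- estimate_ages(cohort$beta, clocks, impute = impute)
  tabs <- list(); fits <- list()
  for (cl in clocks) {
    y <- ages[[cl$name]]
    fit0 <- fit_control_model(y, meta$age_at_recruitment, control_mask)
    acc0 <- compute_acceleration(fit0, y, meta$age_at_recruitment)
    if (has_cells) {
      fit1 <- fit_control_model(y, meta$age_at_recruitment, control_mask,
                                covariates = cohort$cells)
      acc1 <- compute_acceleration(fit1, y, meta$age_at_recruitment,
                                   covariates = cohort$cells)
    } else {
      fit1 <- NULL
      acc1 <- rep(NA_real_, nrow(meta))
    }
    tabs[[cl$name]] <- data.frame(sample_id = meta$sample_id,
                                  clock = cl$name,
                                  dnam_age = y,
                                  age_accel = acc0,
                                  ieaa = acc1,
                                  stringsAsFactors = FALSE)
    fits[[cl$name]] <- list(age_accel = fit0, ieaa = fit1)
  }
  structure(list(table = do.call(rbind, c(tabs, make.row.names = FALSE)),
                 fits = fits, ages = ages,
                 control_ids = meta$sample_id[control_mask]),
            class = "accel_result")
}

#' @export
print.accel_result <- function(x, ...) {
  cat(sprintf("<accel_result> %d samples x %d clock(s), %d fitting controls\n",
              length(unique(x$table$sample_id)), length(x$fits),
              length(x$control_ids)))
  invisible(x)
}
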
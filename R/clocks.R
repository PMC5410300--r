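#' @title Linear epigenetic clocks
#' @description
#' A clock is a linear predictor on CpG beta values:
#' `DNAmAge = g(intercept + sum_i w_i * beta_i)` with `g` either the
#' identity or the two-branch log-linear calibration used by the Horvath
#' multi-tissue clock. Three clocks are built in with their published
#' coefficients: the 3-CpG Weidner blood clock and the single-CpG ELOVL2
#' (cg16867657) and FHL2 (cg06639320) clocks. Larger clocks
#' (Horvath-style 353 CpGs, Hannum-style 71 CpGs) plug in from
#' coefficient files.
#' @name epiclock-clocks
NULL

#' Construct a clock model
#'
#' @param name short clock name (used as a column label downstream).
#' @param weights named numeric vector: probe id -> coefficient, in years
#'   of (possibly transformed) age per unit beta. Names are the clock's
#'   required probes.
#' @param intercept numeric intercept, same scale as the linear predictor.
#' @param transform `"identity"` (the linear combination is the age in
#'   years) or `"horvath_log_linear"` (the linear predictor lives on the
#'   calibrated log-linear scale and is mapped back to years via
#'   [horvath_inverse_transform()]).
#' @param adult_age calibration knot of the log-linear transform, years.
#' @return object of class `clock_model`.
#' @export
#' @examples
#' cl <- clock_model("elovl2", c(cg16867657 = 158.81), -42.35)
#' evaluate_clock(cl, beta_matrix(matrix(0.6, 1, 1,
#'   dimnames = list("cg16867657", "s1"))))
clock_model <- function(name, weights, intercept,
                        transform = c("identity", "horvath_log_linear"),
                        adult_age = 20) {
  transform <- match.arg(transform)
  if (!is.numeric(weights) || !length(weights))
    abort_validation("clock '%s': weights must be a non-empty numeric vector",
                     name)
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    abort_validation("clock '%s': every weight needs a probe id name", name)
  if (anyDuplicated(names(weights)))
    abort_validation("clock '%s': duplicated probe id '%s'", name,
                     names(weights)[duplicated(names(weights))][1L])
  if (any(!is.finite(weights)) || !is.finite(intercept))
    abort_validation("clock '%s': non-finite coefficient", name)
  structure(list(name = name, weights = weights,
                 intercept = as.numeric(intercept),
                 transform = transform, adult_age = adult_age),
            class = "clock_model")
}

#' Probes a clock requires
#' @param model a `clock_model`.
#' @return character vector of probe ids.
#' @export
required_probes <- function(model) names(model$weights)

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %s: %d probe(s), intercept %.4g, %s transform\n",
              x$name, length(x$weights), x$intercept, x$transform))
  invisible(x)
}

#' Built-in clock registry
#'
#' The three clocks whose coefficients are fully published:
#' \describe{
#'   \item{weidner}{3 CpGs: `DNAmAge = 38.0 - 26.4*cg02228185 -
#'     23.7*cg25809905 + 164.7*cg17861230`. Note the middle sign: the
#'     primary report of this model omits the operator before 23.7 in one
#'     rendering; the subtraction used here follows the original
#'     three-probe model's published signs and is the only choice that
#'     maps blood beta profiles onto plausible adult ages.}
#'   \item{elovl2}{`DNAmAge = 158.81 * cg16867657 - 42.35`.}
#'   \item{fhl2}{`DNAmAge = 198.6 * cg06639320 - 30.12`.}
#' }
#' All three use the identity transform.
#'
#' @return named list of `clock_model` objects.
#' @export
builtin_clocks <- function() {
  list(
    weidner = clock_model("weidner",
                          c(cg02228185 = -26.4,
                            cg25809905 = -23.7,
                            cg17861230 = 164.7),
                          intercept = 38.0),
    elovl2 = clock_model("elovl2", c(cg16867657 = 158.81),
                         intercept = -42.35),
    fhl2 = clock_model("fhl2", c(cg06639320 = 198.6),
                       intercept = -30.12)
  )
}

#' Evaluate a clock on a beta matrix
#'
#' Computes `DNAmAge = g(intercept + sum_i w_i * beta_i)` per sample.
#' Every required probe must be present; missing beta values fail by
#' default (naming the sample) unless `impute = TRUE`, in which case a
#' missing value is replaced by that probe's mean across non-missing
#' samples (the pragmatic choice online calculators make for multi-probe
#' clocks).
#'
#' @param model a `clock_model`.
#' @param beta beta matrix (probes x samples).
#' @param impute logical; mean-impute missing required betas per probe.
#' @return named numeric vector of ages in years, one per sample, in the
#'   matrix's column order.
#' @export
evaluate_clock <- function(model, beta, impute = FALSE) {
  stopifnot(inherits(model, "clock_model"))
  beta <- beta_matrix(beta)
  probes <- required_probes(model)
  absent <- setdiff(probes, rownames(beta))
  if (length(absent))
    abort_validation("clock '%s': required probe(s) absent from matrix: %s",
                     model$name, paste(absent, collapse = ", "))
  sub <- beta[probes, , drop = FALSE]
  if (anyNA(sub)) {
    if (impute) {
      for (i in seq_len(nrow(sub))) {
        row <- sub[i, ]
        if (anyNA(row)) {
          if (all(is.na(row)))
            abort_validation("clock '%s': probe '%s' has no observed values",
                             model$name, probes[i])
          row[is.na(row)] <- mean(row, na.rm = TRUE)
          sub[i, ] <- row
        }
      }
    } else {
      j <- which(colSums(is.na(sub)) > 0)[1L]
      abort_validation(
        "clock '%s': missing beta for sample '%s' (enable impute or fix input)",
        model$name, colnames(sub)[j])
    }
  }
  lin <- drop(model$intercept + crossprod(sub, model$weights))
  ages <- switch(model$transform,
                 identity = lin,
                 horvath_log_linear =
                   horvath_inverse_transform(lin, model$adult_age))
  names(ages) <- colnames(beta)
  ages
}

#' Horvath-style log-linear age calibration (forward)
#'
#' Compresses childhood ages logarithmically and leaves adult ages linear:
#' `f(age) = log(age + 1) - log(adult_age + 1)` for `age <= adult_age`,
#' `(age - adult_age) / (adult_age + 1)` otherwise. Continuous and
#' strictly increasing, with `f(adult_age) = 0`.
#'
#' @param age age in years, `> -1`.
#' @param adult_age calibration knot, years (default 20).
#' @return transformed age (unitless).
#' @export
horvath_transform <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' Horvath-style log-linear age calibration (inverse)
#'
#' Maps a clock's linear-predictor output back to years:
#' `(adult_age + 1) * exp(x) - 1` for `x <= 0`, else
#' `(adult_age + 1) * x + adult_age`. Exact two-branch inverse of
#' [horvath_transform()].
#'
#' @param x transformed age, finite.
#' @inheritParams horvath_transform
#' @return age in years.
#' @export
horvath_inverse_transform <- function(x, adult_age = 20) {
  if (any(!is.finite(x)))
    abort_validation("non-finite transformed age")
  ifelse(x <= 0,
         (adult_age + 1) * exp(x) - 1,
         (adult_age + 1) * x + adult_age)
}

#' Load a plug-in clock from a coefficient file
#'
#' The file is delimited text with header columns `probe_id` and
#' `coefficient`, one row per CpG plus exactly one intercept row whose
#' probe_id is the reserved string `"(Intercept)"`. This is the natural
#' exchange format for published clock coefficient tables
#' (Horvath-style 353-CpG, Hannum-style 71-CpG, ...).
#'
#' @param path coefficient file.
#' @param name clock name to assign.
#' @param transform passed to [clock_model()]; use
#'   `"horvath_log_linear"` for clocks trained on the calibrated age
#'   scale.
#' @param delimiter field separator, default comma.
#' @inheritParams clock_model
#' @return a `clock_model`.
#' @export
load_clock_coefficients <- function(path, name,
                                    transform = c("identity",
                                                  "horvath_log_linear"),
                                    delimiter = ",", adult_age = 20) {
  transform <- match.arg(transform)
  df <- read_delim_table(path, delimiter)
  if (!all(c("probe_id", "coefficient") %in% names(df)))
    abort_validation(
      "coefficient file '%s' must have columns probe_id, coefficient", path)
  df$probe_id <- as.character(df$probe_id)
  df$coefficient <- as.numeric(df$coefficient)
  is_int <- df$probe_id == "(Intercept)"
  if (sum(is_int) != 1L)
    abort_validation("coefficient file '%s': need exactly one (Intercept) row, found %d",
                     path, sum(is_int))
  probes <- df$probe_id[!is_int]
  dup <- probes[duplicated(probes)]
  if (length(dup))
    abort_validation("coefficient file '%s': duplicated probe '%s'",
                     path, dup[1L])
  w <- df$coefficient[!is_int]
  names(w) <- probes
  clock_model(name, w, intercept = df$coefficient[is_int],
              transform = transform, adult_age = adult_age)
}

#' Estimate DNAm age for a cohort under several clocks
#'
#' @param beta beta matrix, or a `methyl_cohort`.
#' @param clocks named list of `clock_model`s (default: the built-ins).
#' @param impute passed to [evaluate_clock()].
#' @return data.frame: `sample_id` plus one age column per clock, rows in
#'   the cohort's sample order.
#' @export
estimate_ages <- function(beta, clocks = builtin_clocks(), impute = FALSE) {
  if (inherits(beta, "methyl_cohort")) beta <- beta$beta
  beta <- beta_matrix(beta)
  if (!length(clocks)) abort_validation("no clocks supplied")
  out <- data.frame(sample_id = colnames(beta), stringsAsFactors = FALSE)
  for (cl in clocks) {
    out[[cl$name]] <- unname(evaluate_clock(cl, beta, impute = impute))
  }
  out
}
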
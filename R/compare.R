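#' @title Stratified case-control comparison
#' @description
#' Cases are analyzed per sex x tumor stratum (breast-female, CRC-male,
#' CRC-female; breast-male only when such cases exist). For each stratum
#' an equal-sized control subgroup with matching mean age is drawn at
#' random from the cancer-free pool of the same sex, and case-control
#' differences in acceleration are tested with the two-sided
#' Wilcoxon-Mann-Whitney test — chosen over the t-test because
#' acceleration residuals adhere only imperfectly to normality.
#' @name epiclock-compare
NULL

#' Define sex x tumor strata from metadata
#'
#' Emits one stratum per (tumor, sex) combination that has cases:
#' `breast_female`, `crc_male`, `crc_female` always considered (a warning
#' is raised for any of these with zero cases), `breast_male` only when
#' male breast cases exist. Subjects with outcome `"other"` belong to no
#' stratum and to no control pool.
#'
#' @param meta validated metadata data.frame.
#' @return named list of strata; each has `label`, `outcome`, `sex`,
#'   `case_ids`, `control_pool` (cancer-free ids of the stratum's sex).
#' @export
stratify <- function(meta) {
  meta <- validate_metadata(meta)
  combos <- data.frame(
    outcome = c("breast", "CRC", "CRC", "breast"),
    sex = c("female", "male", "female", "male"),
    canonical = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(combos))) {
    oc <- combos$outcome[i]; sx <- combos$sex[i]
    label <- paste(tolower(oc), sx, sep = "_")
    cases <- meta$sample_id[meta$outcome == oc & meta$sex == sx]
    if (!length(cases)) {
      if (combos$canonical[i])
        warning(sprintf("stratum %s has no cases; skipped", label),
                call. = FALSE)
      next
    }
    pool <- meta$sample_id[meta$outcome == "control" & meta$sex == sx]
    out[[label]] <- list(label = label, outcome = oc, sex = sx,
                         case_ids = cases, control_pool = pool)
  }
  out
}

#' Wilcoxon-Mann-Whitney two-sample test
#'
#' Returns the Mann-Whitney U statistic for `x` (rank-sum minus
#' `n_x(n_x+1)/2`, midranks for ties) and a two-sided p-value. When both
#' groups have at most 10 observations and there are no ties, the exact
#' null distribution is enumerated over all group labelings; otherwise
#' the normal approximation with continuity correction and the tie
#' correction to the variance is used.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with `statistic` (U for `x`), `p_value`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mann_whitney_test(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
mann_whitney_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    abort_validation("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) abort_validation("NA values in test input")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (nx <= 10L && ny <= 10L && !has_ties) {
    # exact: U is a pure function of which ranks land in group x
    combos <- utils::combn(n, nx)
    u_all <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-12)
    method <- "exact"
  } else {
    tt <- table(c(x, y))
    tie_term <- sum(tt^3 - tt)
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "normal"
  }
  list(statistic = U, p_value = p, method = method)
}

# Fast normal-approximation Wilcoxon p (continuity + tie corrected) used
# to score matching draws: the exact enumeration would be re-run up to
# n_draws times inside the selection loop, where its cost is prohibitive
# and its extra precision irrelevant for ranking candidate subsets.
mw_p_normal <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  tt <- tabulate(match(r, unique(r)))
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- max((abs(U - nx * ny / 2) - 0.5) / sqrt(sigma2), 0)
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

#' Randomly select an age-matched control subgroup
#'
#' Mirrors the matching the emulated study describes: a control subgroup
#' of the same size as the case group, with the same mean age, selected
#' at random. Among `n_draws` seeded random subsets of the pool the one
#' maximizing the Wilcoxon p-value of age between cases and candidate
#' controls is kept, provided its case-control mean-age gap is within
#' `tol`; the achieved p and gap are reported as matching diagnostics.
#' If the pool has exactly the case group's size, the whole pool is
#' returned unchanged (nothing to select).
#'
#' @param case_ids character vector of case sample ids.
#' @param control_pool character vector of candidate control ids (must be
#'   at least as many as cases, disjoint from them).
#' @param meta validated metadata (supplies ages).
#' @param seed integer seed for the draws.
#' @param n_draws number of candidate subsets (default 1000).
#' @param tol maximum tolerated |mean age difference| in years
#'   (default 0.5).
#' @return list: `ids` (selected controls) and `diagnostics` (data.frame
#'   with group sizes, mean/median ages, age Wilcoxon p, gap, seed).
#' @export
select_matched_controls <- function(case_ids, control_pool, meta, seed,
                                    n_draws = 1000L, tol = 0.5) {
  meta <- validate_metadata(meta)
  if (length(intersect(case_ids, control_pool)))
    abort_validation("case and control pools overlap")
  if (length(control_pool) < length(case_ids))
    abort_validation("control pool (%d) smaller than case set (%d)",
                     length(control_pool), length(case_ids))
  age <- stats::setNames(meta$age_at_recruitment, meta$sample_id)
  unknown <- setdiff(c(case_ids, control_pool), names(age))
  if (length(unknown))
    abort_validation("id(s) not in metadata: %s",
                     paste(utils::head(unknown, 3L), collapse = ", "))
  age_case <- age[case_ids]
  k <- length(case_ids)

  pick <- function(ids) {
    a <- age[ids]
    list(ids = ids, p = mw_p_normal(age_case, a),
         gap = abs(mean(age_case) - mean(a)))
  }

  if (length(control_pool) == k) {
    best <- pick(control_pool)
  } else {
    best <- NULL
    with_seed(seed, {
      for (i in seq_len(n_draws)) {
        cand <- pick(sample(control_pool, k))
        if (cand$gap <= tol && (is.null(best) || cand$p > best$p))
          best <- cand
      }
    })
    if (is.null(best))
      abort_validation(
        "no control draw within mean-age tolerance %.2f y after %d draws; increase tol or n_draws",
        tol, n_draws)
  }
  if (best$gap > tol)
    abort_validation(
      "matched controls exceed mean-age tolerance: gap %.2f > %.2f y",
      best$gap, tol)
  # report the full test (exact where applicable) for the selected subset
  best$p <- mann_whitney_test(age_case, age[best$ids])$p_value
  diag <- data.frame(
    n_case = k, n_control = length(best$ids),
    mean_age_case = mean(age_case), mean_age_control = mean(age[best$ids]),
    median_age_case = stats::median(age_case),
    median_age_control = stats::median(age[best$ids]),
    age_wilcox_p = best$p, mean_age_gap = best$gap,
    seed = as.integer(seed), n_draws = as.integer(n_draws),
    stringsAsFactors = FALSE)
  list(ids = best$ids, diagnostics = diag)
}

#' Build all strata with matched control subgroups
#'
#' Applies [stratify()] then [select_matched_controls()] per stratum with
#' a stratum-specific seed derived from the master seed. When a stratum's
#' control pool is not larger than its case group the entire pool is used
#' unmatched (as a study does when, e.g., only 84 male controls exist for
#' 87 male CRC cases) and the diagnostics record this.
#'
#' @param meta validated metadata.
#' @param seed master seed.
#' @param n_draws,tol passed to [select_matched_controls()].
#' @return named list of `stratified_cohort` objects: `label`, `outcome`,
#'   `sex`, `case_ids`, `matched_control_ids`, `diagnostics`.
#' @export
build_strata <- function(meta, seed, n_draws = 1000L, tol = 0.5) {
  strata <- stratify(meta)
  out <- list()
  for (st in strata) {
    if (length(st$control_pool) <= length(st$case_ids)) {
      if (!length(st$control_pool)) {
        warning(sprintf("stratum %s has no control pool; skipped", st$label),
                call. = FALSE)
        next
      }
      age <- stats::setNames(meta$age_at_recruitment, meta$sample_id)
      sel <- list(
        ids = st$control_pool,
        diagnostics = data.frame(
          n_case = length(st$case_ids),
          n_control = length(st$control_pool),
          mean_age_case = mean(age[st$case_ids]),
          mean_age_control = mean(age[st$control_pool]),
          median_age_case = stats::median(age[st$case_ids]),
          median_age_control = stats::median(age[st$control_pool]),
          age_wilcox_p = mann_whitney_test(age[st$case_ids],
                                           age[st$control_pool])$p_value,
          mean_age_gap = abs(mean(age[st$case_ids]) -
                               mean(age[st$control_pool])),
          seed = as.integer(seed), n_draws = 0L,
          stringsAsFactors = FALSE))
      message(sprintf(
        "build_strata: %s control pool (%d) <= cases (%d); using full pool unmatched",
        st$label, length(st$control_pool), length(st$case_ids)))
    } else {
      sel <- select_matched_controls(st$case_ids, st$control_pool, meta,
                                     seed = derive_seed(seed,
                                                        paste0("matching_",
                                                               st$label)),
                                     n_draws = n_draws, tol = tol)
    }
    sel$diagnostics <- cbind(stratum = st$label, sel$diagnostics,
                             stringsAsFactors = FALSE)
    out[[st$label]] <- structure(
      list(label = st$label, outcome = st$outcome, sex = st$sex,
           case_ids = st$case_ids, matched_control_ids = sel$ids,
           diagnostics = sel$diagnostics),
      class = "stratified_cohort")
  }
  out
}

#' @export
print.stratified_cohort <- function(x, ...) {
  cat(sprintf("<stratified_cohort> %s: %d cases vs %d matched controls (age gap %.2f y, Wilcox p %.3f)\n",
              x$label, length(x$case_ids), length(x$matched_control_ids),
              x$diagnostics$mean_age_gap, x$diagnostics$age_wilcox_p))
  invisible(x)
}

#' Case-vs-control acceleration tests within a stratum
#'
#' For each clock and measure (Age Accel, IEAA) compares the stratum's
#' cases against its matched controls: group means and medians, the
#' case-minus-control mean difference, and the two-sided
#' Wilcoxon-Mann-Whitney p-value.
#'
#' @param accel an `accel_result` (or its long `$table`).
#' @param stratum a `stratified_cohort`.
#' @param measures subset of `c("age_accel", "ieaa")`.
#' @return data.frame, one row per clock x measure.
#' @export
compare_stratum <- function(accel, stratum,
                            measures = c("age_accel", "ieaa")) {
  tab <- if (inherits(accel, "accel_result")) accel$table else accel
  measures <- match.arg(measures, several.ok = TRUE)
  need <- c(stratum$case_ids, stratum$matched_control_ids)
  missing_ids <- setdiff(need, tab$sample_id)
  if (length(missing_ids))
    abort_validation("acceleration missing for %d stratum member(s), e.g. '%s'",
                     length(missing_ids), missing_ids[1L])
  rows <- list()
  for (cl in unique(tab$clock)) {
    sub <- tab[tab$clock == cl, , drop = FALSE]
    idx <- stats::setNames(seq_len(nrow(sub)), sub$sample_id)
    for (ms in measures) {
      v_case <- sub[[ms]][idx[stratum$case_ids]]
      v_ctrl <- sub[[ms]][idx[stratum$matched_control_ids]]
      if (anyNA(v_case) || anyNA(v_ctrl)) next  # e.g. IEAA without cells
      tst <- mann_whitney_test(v_case, v_ctrl)
      rows[[paste(cl, ms)]] <- data.frame(
        stratum = stratum$label, clock = cl, measure = ms,
        n_case = length(v_case), n_control = length(v_ctrl),
        mean_case = mean(v_case), mean_control = mean(v_ctrl),
        mean_diff = mean(v_case) - mean(v_ctrl),
        median_case = stats::median(v_case),
        median_control = stats::median(v_ctrl),
        p_value = tst$p_value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
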
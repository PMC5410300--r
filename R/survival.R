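#' @title Acceleration and cancer incidence: Kaplan-Meier and log-rank
#' @description
#' Subjects are dichotomized by the sign of their acceleration residual
#' into accelerated (+1) and decelerated (-1) groups, then followed as a
#' right-censored cohort: cases experience the event (cancer diagnosis)
#' at their recorded time to diagnosis, cancer-free controls are censored
#' at a fixed follow-up time — 14.5 years by default, the span from the
#' midpoint of a 1993-1998 recruitment window to a 2010 follow-up close.
#' Group survival is estimated with the Kaplan-Meier product-limit
#' estimator and compared with the Mantel-Haenszel log-rank test (1 df).
#' @name epiclock-survival
NULL

#' Dichotomize residuals into accelerated / decelerated groups
#'
#' `+1` when the residual is `>= 0` (epigenetically at or above the
#' control expectation), `-1` otherwise. A residual of exactly zero — a
#' measure-zero event — is assigned to the accelerated group by
#' convention.
#'
#' @param residuals finite numeric vector of acceleration residuals.
#' @return integer vector of +1 / -1, same length and names.
#' @export
assign_groups <- function(residuals) {
  if (any(!is.finite(residuals)))
    abort_validation("non-finite residual")
  out <- ifelse(residuals >= 0, 1L, -1L)
  names(out) <- names(residuals)
  out
}

#' Fixed censoring time from a recruitment window
#'
#' When individual enrollment dates are unavailable, controls are
#' censored at the average follow-up: end of follow-up minus the midpoint
#' of the recruitment window. With follow-up closing in 2010 and
#' recruitment spanning 1993-1998 this gives 14.5 years.
#'
#' @param follow_up_end calendar year follow-up closed (default 2010).
#' @param recruit_start,recruit_end recruitment window years
#'   (defaults 1993, 1998).
#' @return censoring time in years.
#' @export
derive_censor_time <- function(follow_up_end = 2010,
                               recruit_start = 1993,
                               recruit_end = 1998) {
  follow_up_end - (recruit_start + recruit_end) / 2
}

#' Build right-censored survival records
#'
#' Controls contribute `(censor_time, event = 0)`; cases contribute
#' `(time_to_diagnosis, event = 1)`.
#'
#' @param meta validated metadata rows for the subjects in scope.
#' @param groups named (+1/-1) vector from [assign_groups()], one entry
#'   per subject in `meta` (matched by `sample_id` when named, by
#'   position otherwise).
#' @param censor_time fixed control censoring time in years
#'   (default [derive_censor_time()] = 14.5).
#' @return data.frame: `sample_id`, `time`, `event`, `group`.
#' @export
build_survival_records <- function(meta, groups,
                                   censor_time = derive_censor_time()) {
  meta <- validate_metadata(meta)
  if (!is.null(names(groups))) {
    missing_ids <- setdiff(meta$sample_id, names(groups))
    if (length(missing_ids))
      abort_validation("no group assigned for sample '%s'", missing_ids[1L])
    groups <- groups[meta$sample_id]
  } else if (length(groups) != nrow(meta)) {
    abort_validation("groups length (%d) != number of subjects (%d)",
                     length(groups), nrow(meta))
  }
  if (!all(groups %in% c(-1L, 1L)))
    abort_validation("groups must be +1 or -1")
  is_control <- meta$outcome == "control"
  # validate_metadata already guarantees cases carry a positive
  # time_to_diagnosis and controls none
  data.frame(sample_id = meta$sample_id,
             time = ifelse(is_control, censor_time, meta$time_to_diagnosis),
             event = as.integer(!is_control),
             group = as.integer(groups),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Standard product-limit estimator over the distinct event times. At a
#' tied event/censoring time the censored subjects remain in the risk set
#' (events precede censorings). A group with no events yields the
#' constant function 1.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators (1 = event, 0 = censored).
#' @return data.frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `surv` (the step function's value from that
#'   time on; S(t) = 1 before the first event).
#' @export
km_estimate <- function(time, event) {
  time <- as.numeric(time); event <- as.integer(event)
  stopifnot(length(time) == length(event))
  if (!length(time)) abort_validation("no records")
  if (any(!is.finite(time) | time <= 0))
    abort_validation("times must be positive and finite")
  if (!all(event %in% c(0L, 1L)))
    abort_validation("event must be 0 or 1")
  ev_times <- sort(unique(time[event == 1L]))
  if (!length(ev_times))
    return(data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0)))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), integer(1))
  n_event <- vapply(ev_times, function(t) sum(time == t & event == 1L),
                    integer(1))
  data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
             surv = cumprod(1 - n_event / n_risk))
}

#' Evaluate a Kaplan-Meier fit at arbitrary times
#' @param km data.frame from [km_estimate()].
#' @param t times at which to read the step function.
#' @return survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(ti) {
    past <- km$surv[km$time <= ti]
    if (length(past)) past[length(past)] else 1
  }, numeric(1))
}

#' Mantel-Haenszel log-rank test (two groups, 1 df)
#'
#' Sums observed-minus-expected events for group A over the pooled
#' distinct event times, with the hypergeometric variance at each time;
#' the squared standardized sum is referred to chi-square with 1 df.
#' Undefined (an error, not p = 1) when either group is empty or no
#' events occur at all.
#'
#' @param records_a,records_b data.frames with `time` and `event` columns
#'   (e.g. from [build_survival_records()]).
#' @return list: `chisq`, `p_value`, `observed` / `expected` events in
#'   group A, `n_events`.
#' @export
logrank_test <- function(records_a, records_b) {
  need <- function(df) {
    if (!all(c("time", "event") %in% names(df)))
      abort_validation("records need 'time' and 'event' columns")
    df
  }
  a <- need(records_a); b <- need(records_b)
  if (!nrow(a) || !nrow(b))
    abort_validation("both groups must be non-empty")
  pooled_events <- sort(unique(c(a$time[a$event == 1], b$time[b$event == 1])))
  if (!length(pooled_events))
    abort_validation("log-rank undefined: no events in either group")
  O <- E <- V <- 0
  for (t in pooled_events) {
    n1 <- sum(a$time >= t); n2 <- sum(b$time >= t); n <- n1 + n2
    d1 <- sum(a$time == t & a$event == 1)
    d2 <- sum(b$time == t & b$event == 1)
    d <- d1 + d2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  if (V <= 0)
    abort_validation("log-rank undefined: zero variance")
  chisq <- (O - E)^2 / V
  list(chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = O, expected = E,
       n_events = sum(a$event) + sum(b$event))
}

#' Log-rank p-value matrix across strata, clocks and measures
#'
#' For every stratum (cases plus matched controls pooled) and every
#' clock x measure, splits subjects by acceleration sign and tests the
#' accelerated against the decelerated group's incidence. The result has
#' the shape of the study-style summary table: rows = strata, columns =
#' clock x measure.
#'
#' @param accel_by_stratum named list, stratum label -> `accel_result`
#'   (or long accel table) computed on that stratum's members.
#' @param meta validated metadata for all subjects.
#' @param strata list of `stratified_cohort`s (see [build_strata()]).
#' @param censor_time fixed control censoring time (years).
#' @param measures subset of `c("age_accel", "ieaa")`.
#' @return list: `p_matrix` (strata x clock_measure), `long` (data.frame
#'   with chisq and group sizes), `records` (per stratum/clock/measure
#'   survival records, for plotting).
#' @export
survival_suite <- function(accel_by_stratum, meta, strata,
                           censor_time = derive_censor_time(),
                           measures = c("age_accel", "ieaa")) {
  meta <- validate_metadata(meta)
  measures <- match.arg(measures, several.ok = TRUE)
  rows <- list(); rec_out <- list()
  for (st in strata) {
    tab <- accel_by_stratum[[st$label]]
    if (is.null(tab))
      abort_validation("no acceleration table for stratum '%s'", st$label)
    if (inherits(tab, "accel_result")) tab <- tab$table
    members <- c(st$case_ids, st$matched_control_ids)
    sub_meta <- meta[match(members, meta$sample_id), , drop = FALSE]
    for (cl in unique(tab$clock)) {
      cl_tab <- tab[tab$clock == cl, , drop = FALSE]
      res_lookup <- function(ms)
        stats::setNames(cl_tab[[ms]], cl_tab$sample_id)[members]
      for (ms in measures) {
        res <- res_lookup(ms)
        if (anyNA(res)) next
        grp <- assign_groups(res)
        recs <- build_survival_records(sub_meta, grp, censor_time)
        lr <- logrank_test(recs[recs$group == 1L, , drop = FALSE],
                           recs[recs$group == -1L, , drop = FALSE])
        key <- paste(st$label, cl, ms, sep = ".")
        rec_out[[key]] <- recs
        rows[[key]] <- data.frame(
          stratum = st$label, clock = cl, measure = ms,
          n_accel = sum(grp == 1L), n_decel = sum(grp == -1L),
          chisq = lr$chisq, p_value = lr$p_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  long <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(long))
    abort_validation("no stratum/clock/measure combination could be tested")
  cols <- unique(paste(long$clock, long$measure, sep = "_"))
  strata_labels <- unique(long$stratum)
  p_matrix <- matrix(NA_real_, length(strata_labels), length(cols),
                     dimnames = list(strata_labels, cols))
  for (i in seq_len(nrow(long)))
    p_matrix[long$stratum[i],
             paste(long$clock[i], long$measure[i], sep = "_")] <-
      long$p_value[i]
  list(p_matrix = p_matrix, long = long, records = rec_out)
}
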
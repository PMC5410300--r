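#' @title Full analysis pipeline and command-line driver
#' @description
#' Orchestrates generate/load -> clock estimation -> control-anchored
#' acceleration -> stratified case-control comparison -> survival
#' analysis, writing every result as diff-able delimited text plus a JSON
#' manifest. One master seed drives hierarchically derived per-stage
#' seeds, so identical configs reproduce byte-identical numeric outputs.
#' @name epiclock-pipeline
NULL

#' Pipeline run configuration
#'
#' Exactly one input source must be given: a [synthetic_config()]
#' (simulated cohort) or the three file paths (beta matrix, metadata,
#' cell counts).
#'
#' @param synthetic optional `synthetic_config`.
#' @param beta_path,meta_path,cells_path input files (`cells_path` may be
#'   `NULL`: IEAA is then skipped).
#' @param delimiter input file field separator.
#' @param clocks character vector of built-in clock names to run
#'   (subset of `names(builtin_clocks())`).
#' @param plugins named list of plug-in clocks, each
#'   `list(path = , transform = )` for [load_clock_coefficients()].
#' @param n_draws,tol control-matching parameters (see
#'   [select_matched_controls()]).
#' @param censor_time fixed control censoring time, years.
#' @param fit_scope `"stratum"` (default): anchor each stratum's
#'   acceleration regression on its own matched controls, so residual
#'   centering holds within every comparison; `"pool"`: one fit on the
#'   full control pool.
#' @param impute mean-impute missing betas in multi-probe clocks.
#' @param seed master seed (every stochastic stage derives from it).
#' @param out_dir output directory (created if needed).
#' @return object of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, beta_path = NULL,
                       meta_path = NULL, cells_path = NULL,
                       delimiter = "\t",
                       clocks = names(builtin_clocks()),
                       plugins = list(),
                       n_draws = 1000L, tol = 0.5,
                       censor_time = derive_censor_time(),
                       fit_scope = c("stratum", "pool"),
                       impute = FALSE, seed = 1L, out_dir = "epiclock_out") {
  fit_scope <- match.arg(fit_scope)
  has_files <- !is.null(beta_path) || !is.null(meta_path)
  if (is.null(synthetic) && !has_files)
    abort_validation("provide either a synthetic config or input file paths")
  if (!is.null(synthetic) && has_files)
    abort_validation("provide synthetic config OR file paths, not both")
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config"))
    abort_validation("synthetic must be a synthetic_config")
  if (has_files && (is.null(beta_path) || is.null(meta_path)))
    abort_validation("file input needs both beta_path and meta_path")
  unknown <- setdiff(clocks, names(builtin_clocks()))
  if (length(unknown))
    abort_validation("unknown built-in clock(s): %s (use plugins= for others)",
                     paste(unknown, collapse = ", "))
  if (!length(clocks) && !length(plugins))
    abort_validation("no clocks selected")
  structure(list(synthetic = synthetic, beta_path = beta_path,
                 meta_path = meta_path, cells_path = cells_path,
                 delimiter = delimiter, clocks = clocks, plugins = plugins,
                 n_draws = as.integer(n_draws), tol = tol,
                 censor_time = censor_time, fit_scope = fit_scope,
                 impute = impute, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

resolve_clocks <- function(config) {
  models <- builtin_clocks()[config$clocks]
  for (nm in names(config$plugins)) {
    pl <- config$plugins[[nm]]
    models[[nm]] <- load_clock_coefficients(
      pl$path, nm, transform = pl$transform %||% "identity",
      delimiter = pl$delimiter %||% ",")
  }
  models
}

load_run_cohort <- function(config) {
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- derive_seed(config$seed, "simulate")
    return(generate_cohort(syn))
  }
  cells <- if (is.null(config$cells_path)) NULL
           else read_cell_counts(config$cells_path, config$delimiter)
  align_cohort(read_beta_matrix(config$beta_path, config$delimiter),
               read_metadata(config$meta_path, config$delimiter),
               cells, quiet = TRUE)
}

#' Restrict a cohort to a set of samples
#' @param cohort a `methyl_cohort`.
#' @param ids sample ids to keep (must all exist).
#' @return the restricted `methyl_cohort`.
#' @export
subset_cohort <- function(cohort, ids) {
  stopifnot(inherits(cohort, "methyl_cohort"))
  missing_ids <- setdiff(ids, cohort$sample_ids)
  if (length(missing_ids))
    abort_validation("sample(s) not in cohort: %s",
                     paste(utils::head(missing_ids, 3L), collapse = ", "))
  keep <- sort(unique(ids))
  out <- cohort
  out$beta <- cohort$beta[, keep, drop = FALSE]
  out$meta <- cohort$meta[match(keep, cohort$meta$sample_id), , drop = FALSE]
  rownames(out$meta) <- NULL
  if (!is.null(cohort$cells)) {
    out$cells <- cohort$cells[match(keep, cohort$cells$sample_id), ,
                              drop = FALSE]
    rownames(out$cells) <- NULL
  }
  if (!is.null(cohort$truth)) {
    out$truth <- cohort$truth[match(keep, cohort$truth$sample_id), ,
                              drop = FALSE]
    rownames(out$truth) <- NULL
  }
  out$sample_ids <- keep
  out
}

#' Dry-run configuration diagnostics
#'
#' Checks, without computing anything expensive: input file existence and
#' readability, per-clock probe availability in the beta matrix, plug-in
#' coefficient files, and stratum case/pool sizes. Never throws; every
#' finding is a diagnostic row.
#'
#' @param config a `run_config`.
#' @return list: `ok` (logical) and `diagnostics` (data.frame with
#'   `check`, `status` (`"ok"`/`"fail"`), `detail`).
#' @export
validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  note <- function(check, ok, detail)
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, status = if (ok) "ok" else "fail", detail = detail,
      stringsAsFactors = FALSE)

  beta <- NULL; meta <- NULL
  if (!is.null(config$synthetic)) {
    note("input", TRUE, "synthetic cohort")
    probes <- names(clock_probe_betas(list(weidner = 0, elovl2 = 0,
                                           fhl2 = 0)))
    strata_n <- vapply(config$synthetic$strata,
                       function(st) sprintf("%s %d/%d", st$label,
                                            st$n_cases, st$n_controls),
                       character(1))
    note("strata", TRUE, paste(strata_n, collapse = "; "))
  } else {
    for (fld in c("beta_path", "meta_path", "cells_path")) {
      p <- config[[fld]]
      if (is.null(p)) next
      note(fld, file.exists(p),
           if (file.exists(p)) p else sprintf("missing file: %s", p))
    }
    probes <- character(0)
    if (!is.null(config$beta_path) && file.exists(config$beta_path)) {
      beta <- tryCatch(read_beta_matrix(config$beta_path, config$delimiter),
                       error = function(e) {
                         note("beta_format", FALSE, conditionMessage(e))
                         NULL
                       })
      if (!is.null(beta)) probes <- rownames(beta)
    }
    if (!is.null(config$meta_path) && file.exists(config$meta_path)) {
      meta <- tryCatch(read_metadata(config$meta_path, config$delimiter),
                       error = function(e) {
                         note("meta_format", FALSE, conditionMessage(e))
                         NULL
                       })
      if (!is.null(meta)) {
        for (st in suppressWarnings(stratify(meta)))
          note(paste0("stratum_", st$label),
               length(st$control_pool) > 0,
               sprintf("%d cases, %d-control pool",
                       length(st$case_ids), length(st$control_pool)))
      }
    }
  }
  for (nm in config$clocks) {
    need <- required_probes(builtin_clocks()[[nm]])
    absent <- setdiff(need, probes)
    note(paste0("clock_", nm), length(absent) == 0L,
         if (length(absent)) sprintf("probe(s) absent: %s",
                                     paste(absent, collapse = ", "))
         else "all probes available")
  }
  for (nm in names(config$plugins)) {
    p <- config$plugins[[nm]]$path
    if (is.null(p) || !file.exists(p)) {
      note(paste0("plugin_", nm), FALSE,
           sprintf("missing coefficient file for plug-in clock '%s': %s",
                   nm, p %||% "(no path)"))
      next
    }
    model <- tryCatch(load_clock_coefficients(
      p, nm, transform = config$plugins[[nm]]$transform %||% "identity",
      delimiter = config$plugins[[nm]]$delimiter %||% ","),
      error = function(e) {
        note(paste0("plugin_", nm), FALSE, conditionMessage(e))
        NULL
      })
    if (!is.null(model)) {
      absent <- if (is.null(beta) && !is.null(config$synthetic))
        character(0) else setdiff(required_probes(model), probes)
      note(paste0("plugin_", nm), length(absent) == 0L,
           if (length(absent))
             sprintf("%d required probe(s) absent", length(absent))
           else sprintf("%d probes, ok", length(required_probes(model))))
    }
  }
  diag <- do.call(rbind, c(rows, make.row.names = FALSE))
  list(ok = all(diag$status == "ok"), diagnostics = diag)
}

#' Run the full analysis
#'
#' Stages: load/generate cohort; evaluate the selected clocks; build
#' sex x tumor strata with matched controls; per stratum, fit the
#' control-anchored acceleration regressions and score all members;
#' case-vs-control Wilcoxon tests; accelerated-vs-decelerated
#' Kaplan-Meier / log-rank survival. Writes to `config$out_dir`:
#' `age_estimates.tsv`, `acceleration.tsv`, `group_comparisons.tsv`,
#' `matching_diagnostics.tsv`, `survival_records.tsv`,
#' `survival_pvalues.tsv`, `control_fits.json`, `manifest.json`.
#'
#' @param config a `run_config`.
#' @param quiet suppress per-stage messages.
#' @return (invisibly) list with the in-memory results: `cohort`,
#'   `ages`, `strata`, `accel_by_stratum`, `comparisons`, `survival`,
#'   `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- function(f) file.path(config$out_dir, f)

  say("stage input: loading cohort")
  cohort <- stage("input", load_run_cohort(config))
  models <- stage("clocks", resolve_clocks(config))
  say("stage clocks: %d clock(s) on %d samples", length(models),
      length(cohort$sample_ids))
  ages <- stage("clocks", estimate_ages(cohort$beta, models,
                                        impute = config$impute))
  write_delim_table(ages, paths("age_estimates.tsv"))

  say("stage matching: building strata")
  strata <- stage("matching",
                  build_strata(cohort$meta, seed = config$seed,
                               n_draws = config$n_draws, tol = config$tol))
  if (!length(strata)) abort_validation("[matching] no usable stratum")
  match_diag <- do.call(rbind, c(lapply(strata, `[[`, "diagnostics"),
                                 make.row.names = FALSE))
  write_delim_table(match_diag, paths("matching_diagnostics.tsv"))

  say("stage accel: control-anchored regressions (%s scope)",
      config$fit_scope)
  accel_by_stratum <- list(); accel_rows <- list(); fit_dump <- list()
  for (st in strata) {
    members <- c(st$case_ids, st$matched_control_ids)
    acc <- stage("accel", {
      if (config$fit_scope == "stratum") {
        accel_pipeline(subset_cohort(cohort, members), models,
                       control_ids = st$matched_control_ids,
                       impute = config$impute)
      } else {
        full <- accel_pipeline(cohort, models, impute = config$impute)
        full$table <- full$table[full$table$sample_id %in% members, ,
                                 drop = FALSE]
        full
      }
    })
    accel_by_stratum[[st$label]] <- acc
    accel_rows[[st$label]] <- cbind(stratum = st$label, acc$table,
                                    stringsAsFactors = FALSE)
    fit_dump[[st$label]] <- lapply(acc$fits, function(ff)
      lapply(Filter(Negate(is.null), ff), function(f)
        list(coefficients = as.list(f$coefficients),
             n_controls = f$n_controls, sigma = f$sigma,
             adjusted = f$adjusted)))
  }
  accel_tab <- do.call(rbind, c(accel_rows, make.row.names = FALSE))
  write_delim_table(accel_tab, paths("acceleration.tsv"))
  jsonlite::write_json(fit_dump, paths("control_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("stage compare: case-vs-control Wilcoxon tests")
  comparisons <- stage("compare", do.call(rbind, c(
    lapply(strata, function(st)
      compare_stratum(accel_by_stratum[[st$label]], st)),
    make.row.names = FALSE)))
  write_delim_table(comparisons, paths("group_comparisons.tsv"))

  say("stage survival: Kaplan-Meier / log-rank")
  surv <- stage("survival",
                survival_suite(accel_by_stratum, cohort$meta, strata,
                               censor_time = config$censor_time))
  rec_tab <- do.call(rbind, c(lapply(names(surv$records), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
    cbind(stratum = parts[1L], clock = parts[2L], measure = parts[3L],
          surv$records[[k]], stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
  write_delim_table(rec_tab, paths("survival_records.tsv"))
  pm <- data.frame(stratum = rownames(surv$p_matrix),
                   surv$p_matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_delim_table(pm, paths("survival_pvalues.tsv"))

  manifest <- list(
    package = "epiclock",
    version = as.character(utils::packageVersion("epiclock")),
    r_version = R.version.string,
    seed = config$seed,
    clocks = names(models),
    fit_scope = config$fit_scope,
    censor_time = config$censor_time,
    matching = list(n_draws = config$n_draws, tol = config$tol),
    input = if (is.null(config$synthetic))
      list(beta = config$beta_path, meta = config$meta_path,
           cells = config$cells_path)
    else list(synthetic = unclass(config$synthetic)["seed" != names(unclass(config$synthetic))],
              derived_simulate_seed = derive_seed(config$seed, "simulate")),
    n_samples = length(cohort$sample_ids),
    strata = lapply(strata, function(st)
      list(cases = length(st$case_ids),
           controls = length(st$matched_control_ids))),
    outputs = c("age_estimates.tsv", "acceleration.tsv",
                "group_comparisons.tsv", "matching_diagnostics.tsv",
                "survival_records.tsv", "survival_pvalues.tsv",
                "control_fits.json"))
  jsonlite::write_json(manifest, paths("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("done: outputs in %s", config$out_dir)
  invisible(list(cohort = cohort, ages = ages, strata = strata,
                 accel_by_stratum = accel_by_stratum,
                 comparisons = comparisons, survival = surv,
                 matching_diagnostics = match_diag,
                 paths = vapply(manifest$outputs, paths, character(1))))
}
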
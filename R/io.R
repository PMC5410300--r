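#' @title Core data structures and delimited-text I/O
#' @description
#' The package works from three plain-text inputs that emulate how a GEO
#' HM450 series is usually distributed once preprocessed:
#' a beta-value matrix (CpG probes as rows, samples as columns), a sample
#' metadata table (sex, age at recruitment, outcome, time to diagnosis),
#' and a table of per-sample estimated blood cell counts. All readers
#' validate; all writers emit numeric values at >= 6 significant digits so
#' read/write round-trips are faithful.
#' @name epiclock-io
NULL

VALID_SEX <- c("female", "male")
VALID_OUTCOME <- c("control", "breast", "CRC", "other")

#' The seven leukocyte cell types used as IEAA covariates
#'
#' Naive CD8 T cells, exhausted (CD28-CD45RA-) CD8 T cells, plasma B cells,
#' CD4 T cells, natural killer cells, monocytes and granulocytes: the cell
#' abundance estimates typically returned alongside DNAm age by
#' methylation-based deconvolution. The intrinsic (cell-count adjusted)
#' acceleration regression uses all seven as covariates.
#'
#' @return character vector of the seven column names expected in a cell
#'   count table.
#' @export
blood_cell_types <- function() {
  c("naive_cd8t", "exhausted_cd8t", "plasma_b", "cd4t",
    "natural_killer", "monocytes", "granulocytes")
}

#' Construct and validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix, CpG probes as rows and samples
#' as columns, holding methylated fractions in `[0, 1]`. Missing values are
#' representable as `NA` (never silently imputed at this level); anything
#' outside the unit interval is rejected with the offending probe and
#' sample named.
#'
#' @param values numeric matrix, probes x samples.
#' @param probe_ids,sample_ids row/column identifiers; default to the
#'   dimnames of `values`. Must be unique, non-empty strings.
#' @return the validated numeric matrix with dimnames set.
#' @export
#' @examples
#' beta_matrix(matrix(c(0.1, 0.9), 1, 2,
#'             dimnames = list("cg16867657", c("s1", "s2"))))
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    abort_validation("beta matrix must be numeric")
  if (is.null(probe_ids) || is.null(sample_ids))
    abort_validation("beta matrix needs probe and sample identifiers")
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values))
    abort_validation("identifier lengths do not match matrix dimensions")
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup))
    abort_validation("duplicated probe id: '%s'", dup[1L])
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    abort_validation("duplicated sample id: '%s'", dup[1L])
  if (any(!nzchar(probe_ids)) || any(!nzchar(sample_ids)))
    abort_validation("empty identifier in beta matrix")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    abort_validation(
      "beta value out of [0,1]: %g at probe '%s', sample '%s'",
      values[i, j], probe_ids[i], sample_ids[j])
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  values
}

#' Read a beta-value matrix from delimited text
#'
#' Expected layout (the GEO series-matrix convention): header row
#' `probe_id<delim>sample1<delim>sample2...`, then one probe per row.
#' Empty cells and `NA` become missing values, never zero.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @return validated beta matrix (see [beta_matrix()]).
#' @export
read_beta_matrix <- function(path, delimiter = "\t") {
  df <- read_delim_table(path, delimiter)
  if (ncol(df) < 2L || names(df)[1L] != "probe_id")
    abort_validation(
      "malformed beta matrix header in '%s': first column must be 'probe_id'",
      path)
  probes <- as.character(df[[1L]])
  vals <- df[-1L]
  non_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(non_num))
    abort_validation("non-numeric beta values in column '%s' of '%s'",
                     non_num[1L], path)
  beta_matrix(as.matrix(vals), probes, names(vals))
}

#' Write a beta-value matrix to delimited text
#'
#' @param x beta matrix.
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, delimiter = "\t") {
  x <- beta_matrix(x)
  out <- data.frame(probe_id = rownames(x), as.data.frame(x),
                    check.names = FALSE)
  write_delim_table(out, path, delimiter)
}

#' Validate a sample metadata table
#'
#' Required columns: `sample_id`, `sex` (`female`/`male`),
#' `age_at_recruitment` (years), `outcome` (`control`, `breast`, `CRC`,
#' `other`) and `time_to_diagnosis` (years; present for every case, absent
#' — `NA` — for every control). Controls carrying a diagnosis time, cases
#' missing one, non-positive diagnosis times, and ages outside
#' `age_bounds` are all rejected.
#'
#' @param meta data.frame.
#' @param age_bounds length-2 numeric, plausible adult age range. The
#'   default `[18, 110]` is a sanity bound; the emulated study recruited
#'   at ages 35-64.
#' @return the validated data.frame (columns coerced to canonical types).
#' @export
validate_metadata <- function(meta, age_bounds = c(18, 110)) {
  meta <- as.data.frame(meta)
  req <- c("sample_id", "sex", "age_at_recruitment", "outcome")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols))
    abort_validation("metadata missing column(s): %s",
                     paste(missing_cols, collapse = ", "))
  if (!"time_to_diagnosis" %in% names(meta))
    meta$time_to_diagnosis <- NA_real_
  meta$sample_id <- as.character(meta$sample_id)
  meta$sex <- as.character(meta$sex)
  meta$outcome <- as.character(meta$outcome)
  meta$age_at_recruitment <- as.numeric(meta$age_at_recruitment)
  meta$time_to_diagnosis <- as.numeric(meta$time_to_diagnosis)

  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup))
    abort_validation("duplicated sample id in metadata: '%s'", dup[1L])
  bad <- which(!meta$sex %in% VALID_SEX)
  if (length(bad))
    abort_validation("invalid sex '%s' for sample '%s'",
                     meta$sex[bad[1L]], meta$sample_id[bad[1L]])
  bad <- which(!meta$outcome %in% VALID_OUTCOME)
  if (length(bad))
    abort_validation("invalid outcome '%s' for sample '%s' (allowed: %s)",
                     meta$outcome[bad[1L]], meta$sample_id[bad[1L]],
                     paste(VALID_OUTCOME, collapse = ", "))
  bad <- which(is.na(meta$age_at_recruitment) |
                 meta$age_at_recruitment < age_bounds[1L] |
                 meta$age_at_recruitment > age_bounds[2L])
  if (length(bad))
    abort_validation("age %s outside [%g, %g] for sample '%s'",
                     meta$age_at_recruitment[bad[1L]], age_bounds[1L],
                     age_bounds[2L], meta$sample_id[bad[1L]])
  is_control <- meta$outcome == "control"
  bad <- which(is_control & !is.na(meta$time_to_diagnosis))
  if (length(bad))
    abort_validation("control sample '%s' has a time_to_diagnosis",
                     meta$sample_id[bad[1L]])
  bad <- which(!is_control & is.na(meta$time_to_diagnosis))
  if (length(bad))
    abort_validation("case sample '%s' lacks a time_to_diagnosis",
                     meta$sample_id[bad[1L]])
  bad <- which(!is.na(meta$time_to_diagnosis) & meta$time_to_diagnosis <= 0)
  if (length(bad))
    abort_validation("non-positive time_to_diagnosis for sample '%s'",
                     meta$sample_id[bad[1L]])
  meta[c("sample_id", "sex", "age_at_recruitment", "outcome",
         "time_to_diagnosis")]
}

#' Read a sample metadata table from delimited text
#'
#' @inheritParams read_beta_matrix
#' @inheritParams validate_metadata
#' @return validated metadata data.frame (see [validate_metadata()]).
#' @export
read_metadata <- function(path, delimiter = "\t", age_bounds = c(18, 110)) {
  validate_metadata(read_delim_table(path, delimiter), age_bounds)
}

#' Write a sample metadata table
#' @param meta validated metadata data.frame.
#' @inheritParams write_beta_matrix
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path, delimiter = "\t") {
  write_delim_table(validate_metadata(meta), path, delimiter)
}

#' Validate a blood cell count table
#'
#' One row per sample; all seven columns of [blood_cell_types()] must be
#' present with non-negative finite abundances (the unitless estimates a
#' methylation deconvolution returns; no sum constraint is imposed).
#'
#' @param cells data.frame with `sample_id` plus the seven cell columns.
#' @return validated data.frame in canonical column order.
#' @export
validate_cell_counts <- function(cells) {
  cells <- as.data.frame(cells)
  types <- blood_cell_types()
  missing_cols <- setdiff(c("sample_id", types), names(cells))
  if (length(missing_cols))
    abort_validation("cell count table missing column(s): %s",
                     paste(missing_cols, collapse = ", "))
  cells$sample_id <- as.character(cells$sample_id)
  dup <- cells$sample_id[duplicated(cells$sample_id)]
  if (length(dup))
    abort_validation("duplicated sample id in cell counts: '%s'", dup[1L])
  for (ct in types) {
    cells[[ct]] <- as.numeric(cells[[ct]])
    bad <- which(is.na(cells[[ct]]) | cells[[ct]] < 0)
    if (length(bad))
      abort_validation("invalid %s abundance for sample '%s'",
                       ct, cells$sample_id[bad[1L]])
  }
  cells[c("sample_id", types)]
}

#' Read a blood cell count table from delimited text
#' @inheritParams read_beta_matrix
#' @return validated cell count data.frame.
#' @export
read_cell_counts <- function(path, delimiter = "\t") {
  validate_cell_counts(read_delim_table(path, delimiter))
}

#' Write a blood cell count table
#' @param cells validated cell count data.frame.
#' @inheritParams write_beta_matrix
#' @return `path`, invisibly.
#' @export
write_cell_counts <- function(cells, path, delimiter = "\t") {
  write_delim_table(validate_cell_counts(cells), path, delimiter)
}

#' Join beta matrix, metadata and cell counts into one cohort
#'
#' Intersects sample ids across the inputs (case-sensitive exact match),
#' drops non-shared samples with a report, and canonicalizes sample order
#' (lexicographic), so the result is independent of input ordering and
#' aligning twice is a no-op.
#'
#' @param beta beta matrix.
#' @param meta metadata data.frame.
#' @param cells optional cell count data.frame (`NULL` if intrinsic,
#'   cell-adjusted acceleration is not needed).
#' @param quiet suppress the dropped-sample message.
#' @return an object of class `methyl_cohort`: a list with `beta`, `meta`,
#'   `cells`, `sample_ids` and `dropped` (per-input ids not shared).
#' @export
align_cohort <- function(beta, meta, cells = NULL, quiet = FALSE) {
  beta <- beta_matrix(beta)
  meta <- validate_metadata(meta)
  if (!is.null(cells)) cells <- validate_cell_counts(cells)
  id_sets <- list(beta = colnames(beta), meta = meta$sample_id)
  if (!is.null(cells)) id_sets$cells <- cells$sample_id
  common <- Reduce(intersect, id_sets)
  if (!length(common))
    abort_validation("no sample ids shared across inputs")
  ids <- sort(common)
  dropped <- lapply(id_sets, setdiff, y = common)
  n_drop <- sum(lengths(dropped))
  if (n_drop > 0 && !quiet)
    message(sprintf("align_cohort: dropped %d non-shared sample(s): %s",
                    n_drop,
                    paste(unlist(dropped), collapse = ", ")))
  out <- list(beta = beta[, ids, drop = FALSE],
              meta = meta[match(ids, meta$sample_id), , drop = FALSE],
              cells = if (is.null(cells)) NULL
                      else cells[match(ids, cells$sample_id), , drop = FALSE],
              sample_ids = ids,
              dropped = dropped)
  rownames(out$meta) <- NULL
  if (!is.null(out$cells)) rownames(out$cells) <- NULL
  class(out) <- "methyl_cohort"
  out
}

#' @export
print.methyl_cohort <- function(x, ...) {
  cat(sprintf("<methyl_cohort> %d samples, %d probes%s\n",
              length(x$sample_ids), nrow(x$beta),
              if (is.null(x$cells)) ", no cell counts" else ""))
  cat("outcomes:", paste(sprintf("%s=%d", names(table(x$meta$outcome)),
                                 table(x$meta$outcome)), collapse = " "), "\n")
  invisible(x)
}
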
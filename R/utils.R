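#' Derive a child seed from a master seed and a stage label
#'
#' The pipeline takes a single master seed and gives each stochastic stage
#' (cohort simulation, control matching per stratum, ...) its own derived
#' stream, so any stage can be re-run in isolation and still reproduce the
#' full run. The derivation is a fixed integer hash; results stay below
#' 2^31 so they are valid arguments to [set.seed()].
#'
#' @param seed integer master seed.
#' @param stage character stage label, e.g. `"matching_breast_female"`.
#' @return an integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' derive_seed(1L, "simulate")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 2147483629
  # 48271: the classic Lehmer multiplier; everything stays exact in doubles
  as.integer((abs(seed) %% 2147483629 * 48271 + h * 7919) %% 2147483629)
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Write a delimited table with numeric columns at >= 6 significant digits
# (10 are used so round-trips are faithful well past the stated precision).
write_delim_table <- function(df, path, delimiter = "\t") {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) {
    out <- formatC(col, digits = 10, format = "g")
    out[is.na(col)] <- "NA"
    out
  })
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_delim_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) abort_validation("file not found: '%s'", path)
  utils::read.table(path, sep = delimiter, header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), comment.char = "",
                    quote = "\"")
}
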
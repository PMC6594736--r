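#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published community-ecology
#' tables conventionally round half up, so percentages computed here match
#' printed values (e.g. 25.35 -> 25.4).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count relative to a total, half-up rounded
#'
#' @param n count.
#' @param total reference total (> 0).
#' @param digits decimal places (default 1, the precision used in survey
#'   tables).
#' @return percentage on the 0-100 scale.
#' @export
percentage <- function(n, total, digits = 1) {
  stopifnot(total > 0)
  round_half_up(100 * n / total, digits)
}

# Run expr with a local, restored RNG state. All exported stochastic
# operations funnel through this so no function touches global RNG state
# unless given seed = NULL (in which case the caller's stream is used).
with_seed_local <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic sub-seed for a named pipeline stage. Polynomial string hash
# folded with the master seed, kept inside the 32-bit integer range so it is
# a valid set.seed() argument. Adding a stage never changes other stages'
# sub-seeds.
stage_seed <- function(master_seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(as.numeric(master_seed)) %% 1048573 * 2039 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TSV writer with deterministic column order and 6 significant digits for
# floating point columns.
write_tsv_out <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
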
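#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' printed summary-table cells), unlike [base::round()] which rounds ties to
#' even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(5.75, 1)  # 5.8
#' round_half_up(1.875, 2) # 1.88
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' @keywords internal
#' @noRd
sample_sd <- function(x) stats::sd(x)

# Per-individual sub-seed derived from a single scenario seed.  Keeps every
# individual's draws on its own reproducible stream while staying inside the
# 32-bit integer range R requires for set.seed().
#' @keywords internal
#' @noRd
split_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 2654435761 + i * 7919) %% 2147483647)
}

#' @keywords internal
#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == round(x)

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
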
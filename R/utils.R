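# Centralized rounding and small sequence helpers shared across modules.

#' Round half away from zero
#'
#' All printed-table statistics in this package go through one rounding rule
#' (half-up, as in hand arithmetic) so that reproduced report tables are
#' deterministic across platforms; `base::round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places (may be negative).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Report-precision helpers
#'
#' The report conventions used throughout the summary tables: marker
#' densities per Mb are whole numbers, percentages carry one decimal,
#' ratios two decimals, and fold differences one decimal.
#'
#' @param count marker count.
#' @param size_mb chromosome or genome size in megabases.
#' @return `marker_density()`: integer markers/Mb.
#' @export
marker_density <- function(count, size_mb) {
  stopifnot(all(size_mb > 0))
  round_half_up(count / size_mb, 0)
}

#' @rdname marker_density
#' @param k,n numerator count and total for a percentage.
#' @return `pct_1dp()`: percentage of `n` with one decimal (0 when `n` is 0).
#' @export
pct_1dp <- function(k, n) {
  ifelse(n == 0, 0, round_half_up(100 * k / n, 1))
}

#' @rdname marker_density
#' @param num,den ratio numerator and denominator.
#' @return `ratio_2dp()`: `num/den` with two decimals (`NA` when `den` is 0).
#' @export
ratio_2dp <- function(num, den) {
  ifelse(den == 0, NA_real_, round_half_up(num / den, 2))
}

#' @rdname marker_density
#' @param a,b two positive quantities to compare.
#' @return `fold_1dp()`: `max/min` fold difference with one decimal.
#' @export
fold_1dp <- function(a, b) {
  round_half_up(pmax(a, b) / pmin(a, b), 1)
}

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a base string
#'
#' @param x character vector of A/C/G/T/N strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    paste(rev(unname(COMPLEMENT[strsplit(s, "")[[1]]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Smallest period of a string: p divides nchar(s) and s is a repetition of
# its first p characters.  A motif is "periodic" when its smallest period is
# shorter than itself.
smallest_period <- function(s) {
  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  for (p in seq_len(n)) {
    if (n %% p != 0) next
    if (all(chars == rep_len(chars[seq_len(p)], n))) return(p)
  }
  n
}

is_periodic_motif <- function(s) smallest_period(s) < nchar(s)

assert_bases <- function(x, what = "sequence", allow_n = TRUE) {
  pattern <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pattern, x)
  if (any(bad)) {
    s <- x[which(bad)[1]]
    offset <- regexpr(if (allow_n) "[^ACGTN]" else "[^ACGT]", s)
    abort(sprintf("%s contains a non-IUPAC character at offset %d", what, offset))
  }
  invisible(x)
}

# deterministic per-stage sub-seed derived from a master seed
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(reference = 11L, ssr = 23L, cultivars = 37L, calls = 53L,
               panel = 71L, pipeline = 97L)
  if (!stage %in% names(offsets)) abort(paste("unknown stage:", stage))
  (as.integer(seed) * 127L + offsets[[stage]]) %% .Machine$integer.max
}
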
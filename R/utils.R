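#' Empirical p-value with the add-one convention
#'
#' p = (1 + #\{null >= observed\}) / (n + 1), so a permutation or bootstrap
#' p-value is never exactly zero.
#'
#' @param null numeric vector of null statistics.
#' @param observed scalar observed statistic.
#' @param alternative `"ge"` (null at least as extreme when >= observed) or
#'   `"le"`.
#' @return scalar p-value in (0, 1].
#' @export
empiricalP <- function(null, observed, alternative = c("ge", "le")) {
  alternative <- match.arg(alternative)
  null <- null[!is.na(null)]
  hits <- if (alternative == "ge") sum(null >= observed) else
    sum(null <= observed)
  (1 + hits) / (length(null) + 1)
}

# Draw a derived, reproducible sub-seed (kept < 2^31) so independent
# stochastic stages can share one master seed without lockstep streams.
deriveSeed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% .Machine$integer.max
}

#' @keywords internal
rowMediansNA <- function(x) apply(x, 1L, stats::median, na.rm = TRUE)

# percent with one decimal, used by report arithmetic
pct1 <- function(x) round(100 * x, 1)
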
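#' Compensation report arithmetic from class counts
#'
#' Derives the headline summary quantities of a compensation analysis
#' from its primitive counts: class totals, the collinear fraction of
#' the differentially represented set, the prognosis-concordant
#' fraction, and auxiliary category fractions. All percentages are
#' rounded to one decimal. The inputs can come from a pipeline run or
#' from an already published table of counts.
#'
#' @param n_collinear_loss,n_collinear_gain differentially represented
#'   genes bearing a collinear deletion / gain.
#' @param n_restore_up,n_restore_down,n_enhance_up,n_enhance_down class
#'   counts.
#' @param n_diffrep size of the differentially represented set.
#' @param n_concordant_up,n_concordant_down prognosis-concordant RESTORE
#'   genes per class (optional).
#' @param histone_family_counts enriched histone genes per family
#'   (optional).
#' @param n_apa RESTORE_DOWN genes with alternative-polyadenylation
#'   sites (optional).
#' @param n_half_covered,n_complexes complexes with at least half their
#'   members in the diffrep set, and catalog size (optional).
#' @return list of derived quantities: `n_collinear`,
#'   `collinear_fraction_pct`, `n_restore`, `n_enhance`,
#'   `prevalence` (see [prevalenceTest()]), and where inputs allow
#'   `concordance_pct`, `n_histone_enriched`, `apa_pct`,
#'   `half_covered_pct`.
#' @export
compensationReport <- function(n_collinear_loss, n_collinear_gain,
                               n_restore_up, n_restore_down,
                               n_enhance_up, n_enhance_down,
                               n_diffrep,
                               n_concordant_up = NA,
                               n_concordant_down = NA,
                               histone_family_counts = NULL,
                               n_apa = NA,
                               n_half_covered = NA, n_complexes = NA) {
  n_collinear <- n_collinear_loss + n_collinear_gain
  n_restore <- n_restore_up + n_restore_down
  n_enhance <- n_enhance_up + n_enhance_down
  stopifnot(n_restore + n_enhance == n_collinear)
  out <- list(
    n_collinear = n_collinear,
    n_restore = n_restore,
    n_enhance = n_enhance,
    collinear_fraction_pct = pct1(n_collinear / n_diffrep),
    prevalence = prevalenceTest(n_restore, n_enhance))
  if (!is.na(n_concordant_up) && !is.na(n_concordant_down))
    out$concordance_pct <-
      round(100 * (n_concordant_up + n_concordant_down) / n_restore)
  if (!is.null(histone_family_counts))
    out$n_histone_enriched <- sum(histone_family_counts)
  if (!is.na(n_apa))
    out$apa_pct <- pct1(n_apa / n_restore_down)
  if (!is.na(n_half_covered) && !is.na(n_complexes))
    out$half_covered_pct <- pct1(n_half_covered / n_complexes)
  out
}
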
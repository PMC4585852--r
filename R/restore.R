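#' Classify a gene by its CNA direction and TE direction
#'
#' The four-cell taxonomy of collinear dosage change versus
#' translational-efficiency shift: opposing signs are compensation
#' (RESTORE), matching signs magnification (ENHANCE).
#'
#' \itemize{
#'   \item (loss, up) -> RESTORE_UP: deleted but translationally enhanced
#'   \item (gain, down) -> RESTORE_DOWN: gained but translationally
#'     repressed
#'   \item (gain, up) -> ENHANCE_UP
#'   \item (loss, down) -> ENHANCE_DOWN
#' }
#'
#' @param cna_direction `"loss"` or `"gain"` (vectorized).
#' @param te_direction `"up"` or `"down"` (vectorized).
#' @return character vector of classes.
#' @export
classifyRestore <- function(cna_direction, te_direction) {
  stopifnot(all(cna_direction %in% c("loss", "gain")),
            all(te_direction %in% c("up", "down")))
  ifelse(cna_direction == "loss",
         ifelse(te_direction == "up", "RESTORE_UP", "ENHANCE_DOWN"),
         ifelse(te_direction == "down", "RESTORE_DOWN", "ENHANCE_UP"))
}

#' Classify the differentially represented genes against collinear CNAs
#'
#' Intersects the primary diffrep set with genes holding an unambiguous
#' consensus CNA direction (`"gain"` or `"loss"`; `"none"` and
#' `"conflict"` genes are excluded) and applies [classifyRestore()].
#'
#' @param primary data.frame `gene_id`, `direction` from
#'   [consensusDiffrep()].
#' @param gene_direction data.frame from [assignGeneDirection()].
#' @return data.frame `gene_id`, `cna_direction`, `te_direction`,
#'   `class`, `support`.
#' @export
restoreCalls <- function(primary, gene_direction) {
  gd <- gene_direction[gene_direction$direction %in% c("gain", "loss"), ]
  idx <- match(primary$gene_id, gd$gene_id)
  keep <- !is.na(idx)
  out <- data.frame(gene_id = primary$gene_id[keep],
                    cna_direction = gd$direction[idx[keep]],
                    te_direction = primary$direction[keep],
                    stringsAsFactors = FALSE)
  out$class <- classifyRestore(out$cna_direction, out$te_direction)
  out$support <- gd$support[idx[keep]]
  out
}

#' Exact binomial prevalence test: RESTORE vs ENHANCE
#'
#' Two-sided exact symmetric binomial (p0 = 0.5): the p-value sums the
#' point probabilities not exceeding that of the observed RESTORE count.
#'
#' @param n_restore,n_enhance class totals.
#' @return list: `p`, `n_restore`, `n_enhance`, `prop_restore`.
#' @export
prevalenceTest <- function(n_restore, n_enhance) {
  if (n_restore < 0 || n_enhance < 0) stop("counts must be non-negative")
  n <- n_restore + n_enhance
  if (n < 1) stop("at least one classified gene required")
  p <- stats::binom.test(n_restore, n, 0.5)$p.value
  list(p = p, n_restore = n_restore, n_enhance = n_enhance,
       prop_restore = n_restore / n)
}

#' Enrichment of compensatory genes inside CNAs (Fisher)
#'
#' Tests whether genes with compensatory translational efficiency found
#' in CNAs are enriched with respect to all compensatory genes in the
#' genome: a 2x2 table (compensatory x in-CNA) over the universe, with
#' two-sided Fisher's exact test.
#'
#' @param compensatory gene ids with compensatory TE (genome-wide).
#' @param cna_genes gene ids inside CNA regions.
#' @param universe all analyzable gene ids.
#' @return list: `odds_ratio`, `p`, `table`.
#' @export
compensatoryEnrichment <- function(compensatory, cna_genes, universe) {
  if (!length(universe)) stop("empty universe")
  compensatory <- intersect(compensatory, universe)
  cna_genes <- intersect(cna_genes, universe)
  a <- length(intersect(compensatory, cna_genes))
  b <- length(setdiff(compensatory, cna_genes))
  cc <- length(setdiff(cna_genes, compensatory))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2,
                dimnames = list(comp = c("yes", "no"),
                                cna = c("yes", "no")))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Per-line one-sided rank-sum tests for compensation
#'
#' For each line, tests the two compensation hypotheses against the
#' neutral genes of that line: lost genes should show higher TE
#' (RESTORE_UP family, one-sided greater) and gained genes lower TE
#' (RESTORE_DOWN family, one-sided less). Uses [stats::wilcox.test()]
#' (exact for small strata, normal approximation with tie correction
#' otherwise). Empty strata yield `NA` with a warning.
#'
#' @param te log2 TE matrix ([teMatrix()]).
#' @param calls genes x samples call matrix ([geneCalls()]); rows are
#'   matched to `te` by name.
#' @param adjust apply BH across lines per family.
#' @return data.frame per line: `n_lost`, `n_gained`, `n_neutral`,
#'   `p_restore_up`, `p_restore_down`.
#' @export
perLineWilcoxon <- function(te, calls, adjust = FALSE) {
  calls <- calls[rownames(te), , drop = FALSE]
  res <- lapply(colnames(te), function(s) {
    cl <- calls[, s]
    lost <- te[cl == "loss", s]
    gained <- te[cl %in% c("gain", "amplification"), s]
    neutral <- te[cl == "neutral", s]
    lost <- lost[!is.na(lost)]
    gained <- gained[!is.na(gained)]
    neutral <- neutral[!is.na(neutral)]
    p_up <- p_down <- NA_real_
    if (length(neutral)) {
      if (length(lost)) {
        p_up <- stats::wilcox.test(lost, neutral,
                                   alternative = "greater")$p.value
      } else warning("no lost genes in line ", s)
      if (length(gained)) {
        p_down <- stats::wilcox.test(gained, neutral,
                                     alternative = "less")$p.value
      } else warning("no gained genes in line ", s)
    } else warning("no neutral genes in line ", s)
    data.frame(sample = s, n_lost = length(lost),
               n_gained = length(gained), n_neutral = length(neutral),
               p_restore_up = p_up, p_restore_down = p_down,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust) {
    out$p_restore_up <- stats::p.adjust(out$p_restore_up, "BH")
    out$p_restore_down <- stats::p.adjust(out$p_restore_down, "BH")
  }
  out
}

#' Correlation of per-line compensation strength with TE breadth
#'
#' Pearson correlation of `-log10(p)` (per-line compensation p-values)
#' against the per-line TE distribution breadth (IQR of log2 TE).
#'
#' @param p per-line p-values.
#' @param breadth per-line TE IQR ([teSummary()]`$iqr`).
#' @return list: `r`, `n`; `r` is `NA` with a message when either input
#'   has zero variance.
#' @export
breadthCorrelation <- function(p, breadth) {
  ok <- !is.na(p) & !is.na(breadth)
  if (sum(ok) < 3L) stop("breadth correlation needs >= 3 lines")
  x <- -log10(p[ok])
  y <- breadth[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("zero variance; breadth correlation undefined")
    return(list(r = NA_real_, n = sum(ok)))
  }
  list(r = stats::cor(x, y), n = sum(ok))
}

#' Fisher enrichment of gene categories in a target set
#'
#' One 2x2 Fisher's exact test per category against the universe, BH
#' adjustment across categories, and fold enrichment
#' `(hits / target size) / (category size / universe size)`. Categories
#' disjoint from the universe are skipped with a warning.
#'
#' @param categories named list of gene-id vectors (e.g. from
#'   [readMembershipTable()] or [simulateCatalogs()]).
#' @param target target gene set (non-empty).
#' @param universe gene universe.
#' @return data.frame per category: `n_category`, `n_hits`,
#'   `fold_enrichment`, `odds_ratio`, `p`, `q`.
#' @export
categoryEnrichment <- function(categories, target, universe) {
  if (!length(target)) stop("empty target set")
  target <- intersect(target, universe)
  rows <- lapply(names(categories), function(nm) {
    cat_set <- intersect(categories[[nm]], universe)
    if (!length(cat_set)) {
      warning("category disjoint from universe, skipped: ", nm)
      return(NULL)
    }
    a <- length(intersect(cat_set, target))
    tab <- matrix(c(a, length(target) - a,
                    length(cat_set) - a,
                    length(universe) - length(target) -
                      length(cat_set) + a), 2)
    ft <- stats::fisher.test(tab)
    data.frame(category = nm, n_category = length(cat_set), n_hits = a,
               fold_enrichment = (a / length(target)) /
                 (length(cat_set) / length(universe)),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$q <- stats::p.adjust(out$p, "BH")
  out
}

#' Pan-cancer concordant-alteration bootstrap
#'
#' The observed statistic is the unweighted mean, across the set's genes
#' and all tumor types, of the concordant alteration frequency (loss
#' frequency for RESTORE_UP genes, gain frequency for RESTORE_DOWN).
#' The null repeats the statistic on `n_boot` random same-size gene
#' draws from the chosen background: the whole genome
#' (`mode = "genomewide"`) or the CNA-region genes excluding the RESTORE
#' set (`mode = "cna_background"`). p uses the add-one convention.
#'
#' @param gene_set RESTORE gene ids (one direction).
#' @param freq_table long table from [readFreqTable()] /
#'   [simulateCatalogs()].
#' @param concordant `"loss_freq"` (for RESTORE_UP) or `"gain_freq"`
#'   (for RESTORE_DOWN).
#' @param mode background construction.
#' @param cna_genes gene ids in CNA regions (required for
#'   `"cna_background"`).
#' @param n_boot bootstrap draws (>= 1).
#' @param seed integer seed.
#' @return list: `observed`, `null` (length `n_boot`), `p`, `mode`.
#' @export
panCancerBootstrap <- function(gene_set, freq_table,
                               concordant = c("loss_freq", "gain_freq"),
                               mode = c("genomewide", "cna_background"),
                               cna_genes = NULL, n_boot = 1000L,
                               seed = 1L) {
  concordant <- match.arg(concordant)
  mode <- match.arg(mode)
  if (n_boot < 1L) stop("n_boot must be at least 1")
  set.seed(seed)
  freq <- tapply(freq_table[[concordant]], freq_table$gene_id, mean)
  missing_genes <- setdiff(gene_set, names(freq))
  if (length(missing_genes))
    stop("frequency table does not cover: ", missing_genes[1])
  background <- if (mode == "genomewide") names(freq) else {
    if (is.null(cna_genes)) stop("cna_background mode needs cna_genes")
    setdiff(intersect(cna_genes, names(freq)), gene_set)
  }
  if (length(background) < length(gene_set))
    stop("background smaller than the gene set")
  observed <- mean(freq[gene_set])
  null <- vapply(seq_len(n_boot), function(i)
    mean(freq[sample(background, length(gene_set))]), 0)
  list(observed = observed, null = null,
       p = empiricalP(null, observed), mode = mode)
}
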
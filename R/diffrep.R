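#' Rank-product test for consistent paired fold changes
#'
#' Within each sample, genes are ranked by their paired log2 fold change
#' `fc = TL - TC` (descending for direction `"up"` = polysome-enriched,
#' ascending for `"down"`; ties get average ranks). The rank product
#' `RP(g)` is the geometric mean of the per-sample ranks; a gene
#' consistently near the top of every sample's list gets a small RP.
#' Significance comes from a permutation null: in each of `n_perm`
#' rounds every sample's rank vector is independently shuffled and all
#' null RPs pooled. For each gene the expected number of false positives
#' is the mean count of null RPs at or below its observed RP, and the
#' percentage of false positives (PFP) divides that by the gene's
#' position in the observed RP ranking — an FDR-type error estimate.
#'
#' Because it is rank-based, the statistic is invariant to any monotone
#' transformation of each sample's fold changes.
#'
#' @param fc genes x samples matrix of paired log2 fold changes.
#' @param direction `"up"` or `"down"`.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return data.frame per gene: `gene_id`, `rp`, `e_fp`, `pfp`,
#'   `position` (rank of RP, ascending).
#' @export
rankProductTest <- function(fc, direction = c("up", "down"),
                            n_perm = 1000L, seed = 1L) {
  direction <- match.arg(direction)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (ncol(fc) < 2L) stop("rank product needs >= 2 samples")
  if (any(rowSums(!is.na(fc)) == 0L)) stop("all-missing gene in fc")
  set.seed(seed)
  g <- nrow(fc)
  s <- ncol(fc)
  sgn <- if (direction == "up") -1 else 1
  ranks <- apply(sgn * fc, 2, rank, na.last = "keep")
  logrp <- rowMeans(log(ranks), na.rm = TRUE)
  rp <- exp(logrp)
  # null: independent shuffles of the integer rank vector per sample
  null_logrp <- matrix(0, g, n_perm)
  for (p in seq_len(n_perm)) {
    acc <- numeric(g)
    for (j in seq_len(s)) acc <- acc + log(sample.int(g))
    null_logrp[, p] <- acc / s
  }
  null_sorted <- sort(as.vector(null_logrp))
  e_fp <- findInterval(logrp, null_sorted) / n_perm
  position <- rank(rp, ties.method = "max")
  pfp <- pmin(e_fp / position, 1)
  data.frame(gene_id = rownames(fc), rp = rp, e_fp = e_fp, pfp = pfp,
             position = position, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Paired one-sample t-test per gene
#'
#' One-sample t of the paired fold changes against 0 per gene, two-sided,
#' with Benjamini-Hochberg adjustment across genes. Direction comes from
#' the sign of the mean fold change. A gene with zero variance and a
#' nonzero mean is flagged degenerate and reported at the smallest
#' representable p.
#'
#' @param fc genes x samples matrix of paired log2 fold changes.
#' @return data.frame per gene: `gene_id`, `mean_fc`, `t`, `df`, `p`,
#'   `q`, `direction`, `degenerate`.
#' @export
pairedTTest <- function(fc) {
  n <- rowSums(!is.na(fc))
  if (any(n < 2L)) stop("each gene needs >= 2 non-missing samples")
  m <- rowMeans(fc, na.rm = TRUE)
  sdv <- apply(fc, 1, stats::sd, na.rm = TRUE)
  tt <- m / (sdv / sqrt(n))
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  degenerate <- sdv == 0 & m != 0
  p[degenerate] <- .Machine$double.xmin
  tt[sdv == 0 & m == 0] <- 0
  p[sdv == 0 & m == 0] <- 1
  data.frame(gene_id = rownames(fc), mean_fc = m, t = tt, df = n - 1,
             p = p, q = stats::p.adjust(p, "BH"),
             direction = ifelse(m >= 0, "up", "down"),
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

# SAM fudge factor: the percentile of the per-gene standard errors that
# minimizes the coefficient of variation of the binned scale of d.
chooseS0 <- function(m, se, n_bins = 10L) {
  cand <- unique(stats::quantile(se, seq(0, 1, 0.05), names = FALSE))
  bins <- cut(rank(se, ties.method = "first"), n_bins, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- divSafe(m, se + s0)
    v <- vapply(split(d, bins), function(x) stats::mad(x), 0)
    mv <- mean(v)
    if (!is.finite(mv) || mv == 0) Inf else stats::sd(v) / mv
  }, 0)
  cand[which.min(cv)]
}

# 0/0 arises for all-zero fold changes; the statistic there is 0
divSafe <- function(num, den) ifelse(num == 0 & den == 0, 0, num / den)

#' SAM-style moderated statistic with permutation FDR
#'
#' Computes `d(g) = mean(fc_g) / (s_g + s0)` with `s_g` the per-gene
#' standard error and the fudge factor `s0` chosen by the standard
#' coefficient-of-variation minimization over percentiles of `s_g`. The
#' null is built from `n_perm` sign-flip permutations of the sample
#' columns (the appropriate exchangeability for a one-sample paired
#' design). For a symmetric threshold `delta`, the number of falsely
#' called genes is summarized across permutations (mean by default;
#' `center = "median"` gives the classic formulation, which is markedly
#' anti-conservative for the extreme thresholds where over half of the
#' permutations show zero exceedances) and divided by the observed
#' count beyond `delta`; the smallest `delta` with FDR at or below
#' `fdr` defines the selected set.
#'
#' @param fc genes x samples matrix of paired log2 fold changes.
#' @param n_perm sign-flip permutations (>= 10).
#' @param fdr target FDR for the selection threshold.
#' @param n_bins bins for the `s0` search.
#' @param center summary of the null exceedance counts: `"mean"`
#'   (default, calibrated under a global null) or `"median"`.
#' @param seed integer seed.
#' @return list: `table` (per-gene `d`, `se`, `direction`, `selected`),
#'   `s0`, `delta` (chosen threshold, `Inf` if no threshold reaches the
#'   target), `fdr_table` (scanned thresholds and their FDR estimates).
#' @export
samTest <- function(fc, n_perm = 200L, fdr = 0.05, n_bins = 10L,
                    center = c("mean", "median"), seed = 1L) {
  center <- match.arg(center)
  if (n_perm < 10L) stop("n_perm must be at least 10")
  if (ncol(fc) < 3L) stop("SAM needs >= 3 samples")
  set.seed(seed)
  n <- rowSums(!is.na(fc))
  m <- rowMeans(fc, na.rm = TRUE)
  se <- apply(fc, 1, stats::sd, na.rm = TRUE) / sqrt(n)
  s0 <- chooseS0(m, se, n_bins)
  d <- divSafe(m, se + s0)
  null_abs <- matrix(0, nrow(fc), n_perm)
  for (p in seq_len(n_perm)) {
    eps <- sample(c(-1, 1), ncol(fc), replace = TRUE)
    fcp <- sweep(fc, 2, eps, `*`)
    mp <- rowMeans(fcp, na.rm = TRUE)
    sep <- apply(fcp, 1, stats::sd, na.rm = TRUE) / sqrt(n)
    null_abs[, p] <- abs(divSafe(mp, sep + s0))
  }
  centerFun <- if (center == "mean") mean else stats::median
  deltas <- sort(unique(abs(d)), decreasing = FALSE)
  n_obs <- vapply(deltas, function(dl) sum(abs(d) >= dl), 0L)
  n_null <- vapply(deltas, function(dl)
    centerFun(colSums(null_abs >= dl)), 0)
  fdr_est <- pmin(ifelse(n_obs == 0, 0, n_null / n_obs), 1)
  ok <- which(fdr_est <= fdr & n_obs > 0)
  delta <- if (length(ok)) deltas[min(ok)] else Inf
  selected <- abs(d) >= delta
  list(table = data.frame(gene_id = rownames(fc), d = d, se = se,
                          direction = ifelse(d >= 0, "up", "down"),
                          selected = selected, row.names = NULL,
                          stringsAsFactors = FALSE),
       s0 = s0, delta = delta,
       fdr_table = data.frame(delta = deltas, n_obs = n_obs,
                              n_null = n_null, fdr = fdr_est))
}

#' Run all three differential-representation methods on a paired design
#'
#' @param pe a [PairedExpression-class]; fold changes are
#'   `translatome - transcriptome` per line ([teMatrix()]).
#' @param genes gene universe (default [detectableGenes()]).
#' @param config a [simConfig()] configuration (permutation counts and
#'   thresholds are read from it).
#' @return list with `rp_up`, `rp_down`, `t`, `sam`, and `fc`.
#' @export
diffRepAll <- function(pe, genes = detectableGenes(pe),
                       config = simConfig()) {
  fc <- teMatrix(pe)[genes, , drop = FALSE]
  list(fc = fc,
       rp_up = rankProductTest(fc, "up", config$rp_n_perm,
                               deriveSeed(config$seed, 11L)),
       rp_down = rankProductTest(fc, "down", config$rp_n_perm,
                                 deriveSeed(config$seed, 12L)),
       t = pairedTTest(fc),
       sam = samTest(fc, n_perm = config$sam_n_perm,
                     fdr = config$sam_fdr, n_bins = config$sam_bins,
                     seed = deriveSeed(config$seed, 13L)))
}

#' Consensus of the three differential-representation methods
#'
#' Builds the 7-region Venn decomposition of the three selected sets and
#' the primary set: rank-product-significant genes (PFP at or below the
#' threshold in either direction) with their direction labels. A gene
#' significant in both rank-product directions is impossible by
#' construction and asserted. Also reports the share of the primary set
#' confirmed by all three methods.
#'
#' @param diffrep result of [diffRepAll()].
#' @param pfp_threshold rank-product PFP cut.
#' @param q_threshold BH q cut for the t-test.
#' @return list: `primary` (data.frame gene_id, direction, pfp),
#'   `sets` (the three selected sets), `venn` (named 7-region counts),
#'   `share_all_three` (fraction of the primary set in the triple
#'   overlap).
#' @export
consensusDiffrep <- function(diffrep, pfp_threshold = 0.05,
                             q_threshold = 0.05) {
  up <- diffrep$rp_up$gene_id[diffrep$rp_up$pfp <= pfp_threshold]
  down <- diffrep$rp_down$gene_id[diffrep$rp_down$pfp <= pfp_threshold]
  both <- intersect(up, down)
  stopifnot("gene significant in both rank-product directions" =
              length(both) == 0L)
  rp_set <- c(up, down)
  t_set <- diffrep$t$gene_id[diffrep$t$q <= q_threshold]
  sam_set <- diffrep$sam$table$gene_id[diffrep$sam$table$selected]
  universe <- diffrep$rp_up$gene_id
  if (!all(t_set %in% universe) || !all(sam_set %in% universe))
    stop("method results cover different gene universes")
  inA <- universe %in% rp_set
  inB <- universe %in% t_set
  inC <- universe %in% sam_set
  venn <- c(rp_only = sum(inA & !inB & !inC),
            t_only = sum(!inA & inB & !inC),
            sam_only = sum(!inA & !inB & inC),
            rp_t = sum(inA & inB & !inC),
            rp_sam = sum(inA & !inB & inC),
            t_sam = sum(!inA & inB & inC),
            all_three = sum(inA & inB & inC))
  pfp <- c(stats::setNames(diffrep$rp_up$pfp, diffrep$rp_up$gene_id)[up],
           stats::setNames(diffrep$rp_down$pfp,
                           diffrep$rp_down$gene_id)[down])
  primary <- data.frame(gene_id = rp_set,
                        direction = rep(c("up", "down"),
                                        c(length(up), length(down))),
                        pfp = unname(pfp), stringsAsFactors = FALSE)
  share <- if (length(rp_set))
    sum(rp_set %in% intersect(t_set, sam_set)) / length(rp_set) else NA_real_
  list(primary = primary,
       sets = list(rankprod = rp_set, ttest = t_set, sam = sam_set),
       venn = venn, share_all_three = share)
}
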
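#' Filter probes on QC flags and summarize to genes
#'
#' Keeps a probe iff it is above background in at least
#' `fractions["above_background"]` of samples, a good spot (sufficient
#' diameter and signal-to-noise) in at least `fractions["good_spot"]` of
#' samples, and never saturated or an outlier in any sample. Duplicate
#' probes per gene are then summarized by the per-sample median.
#'
#' @param mat probes x samples log2 matrix.
#' @param flags list of logical probes x samples matrices:
#'   `above_background`, `good_spot`, `saturated`, `outlier` (missing
#'   flags default to passing).
#' @param probe_gene character vector mapping each probe (row) to a gene
#'   id; defaults to rownames (one probe per gene).
#' @param fractions named fractions in \[0, 1\].
#' @return genes x samples matrix of kept, summarized probes.
#' @export
filterProbes <- function(mat, flags = list(),
                         probe_gene = rownames(mat),
                         fractions = c(above_background = 0.25,
                                       good_spot = 0.75)) {
  if (any(fractions < 0 | fractions > 1))
    stop("filter fractions must lie in [0, 1]")
  force(probe_gene)
  n_s <- ncol(mat)
  flag <- function(name, default) {
    f <- flags[[name]]
    if (is.null(f)) matrix(default, nrow(mat), n_s) else {
      stopifnot(identical(dim(f), dim(mat)))
      f
    }
  }
  keep <- rowMeans(flag("above_background", TRUE)) >=
    fractions[["above_background"]] &
    rowMeans(flag("good_spot", TRUE)) >= fractions[["good_spot"]] &
    rowSums(flag("saturated", FALSE)) == 0 &
    rowSums(flag("outlier", FALSE)) == 0
  mat <- mat[keep, , drop = FALSE]
  genes <- probe_gene[keep]
  if (anyDuplicated(genes)) {
    out <- do.call(rbind, lapply(split(seq_along(genes), genes),
                                 function(i)
                                   apply(mat[i, , drop = FALSE], 2,
                                         stats::median, na.rm = TRUE)))
    out[order(match(rownames(out), genes)), , drop = FALSE]
  } else {
    rownames(mat) <- genes
    mat
  }
}

#' Quantile-normalize a log2 expression matrix
#'
#' Each sample's sorted values are replaced by the across-sample mean of
#' order statistics; ties receive the average of the values they would be
#' assigned. Delegates to [limma::normalizeQuantiles()] (with
#' `ties = TRUE`), the standard implementation of exactly this procedure.
#'
#' @param mat genes x samples matrix (at least 2 samples).
#' @return normalized matrix of the same shape.
#' @export
normalizeQuantile <- function(mat) {
  if (ncol(mat) < 2L) stop("quantile normalization needs >= 2 samples")
  if (any(colSums(!is.na(mat)) == 0L))
    stop("all-missing sample: ",
         colnames(mat)[colSums(!is.na(mat)) == 0][1])
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Detectable (expressed) genes
#'
#' A gene is detectable at one level iff its median across samples is at
#' least the first quartile of all gene medians (linear-interpolation
#' quartile, R type 7 by default — pinned so results are reproducible).
#' For a [PairedExpression-class] the rule is applied per level and the
#' union is taken, so genes silenced at a single level remain analyzable.
#'
#' @param x a matrix or a `PairedExpression`.
#' @param quartile_type R quantile type (default 7).
#' @return character vector of detectable gene ids.
#' @export
detectableGenes <- function(x, quartile_type = 7L) {
  if (methods::is(x, "PairedExpression")) {
    return(sort(union(detectableGenes(transcriptome(x), quartile_type),
                      detectableGenes(translatome(x), quartile_type))))
  }
  med <- rowMediansNA(x)
  q1 <- stats::quantile(med, 0.25, type = quartile_type, names = FALSE)
  rownames(x)[med >= q1]
}

#' Translational efficiency matrix
#'
#' TE is the ratio of translatome to transcriptome abundance, carried in
#' log2: `TE = log2(TL) - log2(TC)`, so 0 means equal levels, positive
#' values translational enhancement and negative values repression.
#' Defined only where both levels are present (`NA` otherwise).
#'
#' @param x a [PairedExpression-class] object.
#' @return genes x samples numeric matrix of log2 TE.
#' @seealso [teSummary()] for per-sample distribution summaries.
#' @export
teMatrix <- function(x) {
  stopifnot(methods::is(x, "PairedExpression"))
  translatome(x) - transcriptome(x)
}

#' Per-sample TE distribution summaries
#'
#' @param te log2 TE matrix from [teMatrix()].
#' @return data.frame per sample: `median`, `iqr` (the distribution
#'   breadth used by [breadthCorrelation()]), and the tail fractions of
#'   genes beyond +/-1 log2 (2-fold enhancement / repression).
#' @export
teSummary <- function(te) {
  data.frame(
    sample = colnames(te),
    median = apply(te, 2, stats::median, na.rm = TRUE),
    iqr = apply(te, 2, stats::IQR, na.rm = TRUE),
    frac_enhanced = colMeans(te > 1, na.rm = TRUE),
    frac_repressed = colMeans(te < -1, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster transcriptome and translatome profiles jointly
#'
#' Builds the combined profile matrix (both levels side by side over the
#' detectable genes), computes the Pearson-correlation distance
#' (`1 - r`), and runs Ward hierarchical clustering, k-means on the
#' profiles and PCA. The headline readout is how many translatome
#' profiles have their nearest profile (correlation distance) among the
#' other translatomes rather than their own transcriptome's level —
#' i.e. whether translational control, not cell-line identity, dominates
#' profile similarity.
#'
#' @param pe a [PairedExpression-class] object.
#' @param genes gene ids to use (default: [detectableGenes()]).
#' @param k k-means cluster count.
#' @param nstart k-means restarts.
#' @param seed integer seed for k-means.
#' @return list: `hclust`, `kmeans`, `pca` (prcomp), `dist`,
#'   `tl_coclustered` (count of translatome profiles nearest another
#'   translatome), `labels` (profile level labels).
#' @export
clusterProfiles <- function(pe, genes = detectableGenes(pe), k = 3L,
                            nstart = 20L, seed = 1L) {
  tc <- transcriptome(pe)[genes, , drop = FALSE]
  tl <- translatome(pe)[genes, , drop = FALSE]
  prof <- cbind(tc, tl)
  colnames(prof) <- c(paste0(colnames(tc), ".TC"),
                      paste0(colnames(tl), ".TL"))
  sds <- apply(prof, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0))
    stop("constant profile (zero variance): ",
         colnames(prof)[sds == 0][1])
  if (ncol(prof) < 3L) stop("profile clustering needs >= 3 profiles")
  cors <- stats::cor(prof, use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - cors)
  hc <- stats::hclust(d, method = "ward.D")
  set.seed(seed)
  km <- stats::kmeans(t(prof), centers = k, nstart = nstart)
  pca <- stats::prcomp(t(prof))
  level <- rep(c("TC", "TL"), each = ncol(tc))
  dm <- as.matrix(d)
  diag(dm) <- Inf
  nearest <- apply(dm, 1, which.min)
  tl_idx <- which(level == "TL")
  tl_co <- sum(level[nearest[tl_idx]] == "TL")
  list(hclust = hc, kmeans = km, pca = pca, dist = d,
       tl_coclustered = tl_co, labels = level)
}

#' Delta-CT qPCR normalization with a multi-gene reference
#'
#' Relative level = `2^-(CT_target - mean(CT_references))`; replicate CT
#' measurements are averaged first. Using the arithmetic mean of the
#' reference CTs corresponds to the geometric mean of their linear-scale
#' levels.
#'
#' @param ct data.frame with columns `gene`, `sample`, `ct` (replicates
#'   as repeated rows).
#' @param reference_ids reference gene ids (all must be present in every
#'   sample).
#' @return genes x samples matrix of relative expression levels.
#' @export
normalizeQpcr <- function(ct, reference_ids) {
  missing_ref <- setdiff(reference_ids, ct$gene)
  if (length(missing_ref))
    stop("reference gene(s) absent from CT table: ",
         paste(missing_ref, collapse = ", "))
  avg <- stats::aggregate(ct ~ gene + sample, data = ct, FUN = mean)
  m <- stats::xtabs(ct ~ gene + sample, data = avg)
  m <- as.matrix(unclass(m))
  if (any(is.na(m[reference_ids, ])))
    stop("reference gene missing in some sample")
  ref <- colMeans(m[reference_ids, , drop = FALSE])
  2^-(sweep(m, 2, ref))
}
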
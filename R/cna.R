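# Outlier smoothing: probes deviating from their running-median
# neighbourhood by more than k * MAD are winsorized to that bound.
smoothOutliers <- function(x, width = 5L, k = 4) {
  if (length(x) < width) return(x)
  med <- stats::runmed(x, width, endrule = "median")
  resid <- x - med
  s <- stats::mad(resid)
  if (s == 0) return(x)
  pmin(pmax(x, med - k * s), med + k * s)
}

# max two-sample t between an arc (i, j] and its complement, over all
# admissible breakpoint pairs. Testing arcs (as circular binary
# segmentation does) lets a short altered run inside a long segment be
# found in one step, where a single binary split would dilute it.
# Admissible: arc and complement each >= min_probes, and neither flank
# (left of i, right of j) is a fragment shorter than min_probes.
# Arc geometry shared by every permutation of a segment of length n:
# admissible (i, j] pairs, arc lengths and the t-statistic weights.
arcCache <- function(n, min_probes) {
  iv <- unique(c(0L, seq.int(min_probes, n - min_probes)))
  jv <- unique(c(seq.int(min_probes, n - min_probes), n))
  ni <- length(iv)
  nj <- length(jv)
  I <- matrix(iv, ni, nj)
  J <- matrix(jv, ni, nj, byrow = TRUE)
  L <- J - I
  ok <- L >= min_probes & (n - L) >= min_probes
  L[!ok] <- 1L  # masked below; avoids divide-by-zero on invalid pairs
  n2 <- n - L
  list(n = n, iv = iv + 1L, jv = jv + 1L, I = I, J = J, L = L, n2 = n2,
       ok = ok, w = 1 / L + 1 / n2)
}

arcStat <- function(x, cache) {
  n <- cache$n
  cs <- c(0, cumsum(x))
  css <- c(0, cumsum(x^2))
  CSi <- matrix(cs[cache$iv], nrow(cache$I), ncol(cache$I))
  CSj <- matrix(cs[cache$jv], nrow(cache$I), ncol(cache$I), byrow = TRUE)
  SSi <- matrix(css[cache$iv], nrow(cache$I), ncol(cache$I))
  SSj <- matrix(css[cache$jv], nrow(cache$I), ncol(cache$I), byrow = TRUE)
  m1 <- (CSj - CSi) / cache$L
  m2 <- (cs[n + 1] - CSj + CSi) / cache$n2
  ss <- (SSj - SSi) - cache$L * m1^2 +
    (css[n + 1] - SSj + SSi) - cache$n2 * m2^2
  sp2 <- pmax(ss / (n - 2), .Machine$double.eps)
  tt <- abs(m1 - m2) / sqrt(sp2 * cache$w)
  tt[!cache$ok] <- -Inf
  k <- which.max(tt)
  list(i = cache$I[k], j = cache$J[k], stat = tt[k], resid_ss = ss[k],
       total_ss = css[n + 1] - cs[n + 1]^2 / n)
}

maxArcT <- function(x, min_probes) arcStat(x, arcCache(length(x),
                                                       min_probes))

#' Segment an ordered log-ratio track
#'
#' Recursive circular binary segmentation: after winsorizing outliers
#' against a running-median neighbourhood, each segment is split at the
#' arc (breakpoint pair) maximizing the two-sample t statistic between
#' the arc and its complement; the split is accepted when its
#' within-segment permutation p-value (add-one convention) falls below
#' `alpha` and every resulting piece holds at least `min_probes` probes,
#' then the pieces are segmented recursively. An arc anchored at either
#' segment end reduces to an ordinary binary split.
#'
#' @param position strictly increasing probe positions (one chromosome).
#' @param value probe log2 ratios.
#' @param alpha split significance level.
#' @param min_probes minimum probes per segment.
#' @param n_perm within-segment permutations per candidate split.
#' @param seed integer seed for the permutation stream.
#' @param smooth_window,smooth_k outlier winsorization tunables.
#' @return data.frame with `start_index`, `end_index`, `start`, `end`
#'   (probe positions), `n_probes`, `mean` (of the unsmoothed values).
#' @export
segmentProfile <- function(position, value, alpha = 0.01, min_probes = 5L,
                           n_perm = 100L, seed = 1L, smooth_window = 5L,
                           smooth_k = 4) {
  if (is.unsorted(position, strictly = TRUE))
    stop("probe positions must be strictly increasing")
  if (length(position) != length(value))
    stop("position and value lengths differ")
  n <- length(value)
  if (n < min_probes)
    warning("fewer probes (", n, ") than min_probes; returning one segment")
  set.seed(seed)
  x <- smoothOutliers(value, smooth_window, smooth_k)
  bounds <- list()
  recurse <- function(lo, hi) {
    if (hi - lo + 1L < 2L * min_probes || stats::var(x[lo:hi]) == 0) {
      bounds[[length(bounds) + 1L]] <<- c(lo, hi)
      return(invisible())
    }
    seg <- x[lo:hi]
    cache <- arcCache(length(seg), min_probes)
    obs <- arcStat(seg, cache)
    # degenerate input: a split explaining all within-segment variance
    # (noise-free step) is accepted outright; the permutation test is
    # only meaningful when residual variance remains
    exact_fit <- obs$resid_ss <= 1e-12 * obs$total_ss
    p <- if (exact_fit) 0 else {
      null <- vapply(seq_len(n_perm), function(p)
        arcStat(sample(seg), cache)$stat, 0)
      empiricalP(null, obs$stat)
    }
    if (p < alpha) {
      if (obs$i > 0L) recurse(lo, lo + obs$i - 1L)
      recurse(lo + obs$i, lo + obs$j - 1L)
      if (lo + obs$j <= hi) recurse(lo + obs$j, hi)
    } else {
      bounds[[length(bounds) + 1L]] <<- c(lo, hi)
    }
    invisible()
  }
  recurse(1L, n)
  b <- do.call(rbind, bounds)
  b <- b[order(b[, 1]), , drop = FALSE]
  data.frame(start_index = b[, 1], end_index = b[, 2],
             start = position[b[, 1]], end = position[b[, 2]],
             n_probes = b[, 2] - b[, 1] + 1L,
             mean = vapply(seq_len(nrow(b)), function(i)
               mean(value[b[i, 1]:b[i, 2]]), 0))
}

#' Re-center a segmented profile at its most likely neutral level
#'
#' Subtracts the mode of the probe-weighted kernel density of segment
#' means from all means, adapting each sample's profile to its most
#' likely zero value. With a single segment the shift is its mean.
#'
#' @param segments data.frame with `mean` and `n_probes` (one sample),
#'   e.g. rbind-ed [segmentProfile()] output over chromosomes.
#' @param bw kernel bandwidth (log2 units).
#' @return `segments` with shifted `mean` and an attribute `"shift"`.
#' @export
recenterProfile <- function(segments, bw = 0.1) {
  m <- segments$mean
  w <- segments$n_probes / sum(segments$n_probes)
  shift <- if (length(m) == 1L) m else {
    d <- stats::density(m, weights = w, bw = bw, n = 2048L)
    d$x[which.max(d$y)]
  }
  segments$mean <- m - shift
  attr(segments, "shift") <- shift
  segments
}

#' Call copy-number state from re-centered segment means
#'
#' Fixed-threshold calling: `mean < -t_loss` is a loss, `mean > t_amp` an
#' amplification, `mean > t_gain` a gain, anything else neutral.
#'
#' @param segments data.frame with a `mean` column (re-centered).
#' @param t_loss,t_gain,t_amp log2-ratio thresholds; requires
#'   `t_gain < t_amp`.
#' @return `segments` with a `call` column in
#'   `{loss, neutral, gain, amplification}`.
#' @export
callSegments <- function(segments, t_loss = 0.2, t_gain = 0.2,
                         t_amp = 1.0) {
  if (t_gain >= t_amp)
    stop("calling thresholds must satisfy t_gain < t_amp")
  m <- segments$mean
  segments$call <- ifelse(m < -t_loss, "loss",
                          ifelse(m > t_amp, "amplification",
                                 ifelse(m > t_gain, "gain", "neutral")))
  segments
}

#' Gene-level copy-number calls from called segments
#'
#' Assigns each gene the call of the segment covering its midpoint, per
#' sample. Genes not covered by any segment are neutral.
#'
#' @param segments `GRanges` with `sample` and `call` metadata (e.g. from
#'   [readSeg()] or assembled from [callSegments()] output).
#' @param annotation gene `GRanges` from [readAnnotation()].
#' @return character matrix genes x samples of calls.
#' @export
geneCalls <- function(segments, annotation) {
  mids <- GenomicRanges::resize(annotation, width = 1L, fix = "center")
  samples <- unique(segments$sample)
  out <- matrix("neutral", length(annotation), length(samples),
                dimnames = list(annotation$gene_id, samples))
  for (s in samples) {
    seg <- segments[segments$sample == s]
    hit <- GenomicRanges::findOverlaps(mids, seg, select = "first")
    ok <- !is.na(hit)
    out[ok, s] <- seg$call[hit[ok]]
  }
  out
}

#' Consensus copy-number direction per gene across samples
#'
#' A gene's direction is the sign shared by all of its non-neutral calls
#' (amplification counting as gain): `"gain"` or `"loss"` with the
#' supporting sample count, `"conflict"` when both signs occur (such
#' genes are excluded downstream), `"none"` when every call is neutral.
#'
#' @param calls character matrix genes x samples from [geneCalls()].
#' @return data.frame with `gene_id`, `direction`, `support`.
#' @export
assignGeneDirection <- function(calls) {
  gains <- rowSums(calls == "gain" | calls == "amplification")
  losses <- rowSums(calls == "loss")
  direction <- ifelse(gains > 0 & losses > 0, "conflict",
                      ifelse(gains > 0, "gain",
                             ifelse(losses > 0, "loss", "none")))
  data.frame(gene_id = rownames(calls), direction = direction,
             support = pmax(gains, losses), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Recurrent aberrations by count statistic with a rotation null
#'
#' Per gene, the statistic is the larger of the gain-supporting and
#' loss-supporting sample counts (amplification counts as gain). The
#' null preserves each sample's spatial run structure by cyclically
#' shifting its genome-ordered call track (within each permutation every
#' sample gets an independent random rotation). Genes with
#' `count >= min_recurrence` and BH-adjusted rotation p-value at or below
#' `fdr` are flagged and merged into regions by genomic adjacency.
#'
#' @param calls genes x samples call matrix, rows in genome order.
#' @param annotation gene `GRanges` aligned to `calls` rows.
#' @param min_recurrence minimum concordant sample count.
#' @param n_perm number of rotation permutations.
#' @param seed integer seed.
#' @param fdr BH threshold on the rotation p-values.
#' @return list with `genes` (per-gene count, direction, p, q, flagged)
#'   and `regions` (merged flagged runs with chrom, bounds, direction).
#' @export
recurrentAberrations <- function(calls, annotation, min_recurrence = 5L,
                                 n_perm = 200L, seed = 1L, fdr = 0.05) {
  if (ncol(calls) < 2L) stop("recurrence needs calls for >= 2 samples")
  if (min_recurrence > ncol(calls))
    stop("min_recurrence exceeds the number of samples")
  set.seed(seed)
  num <- matrix(0L, nrow(calls), ncol(calls))
  num[calls == "gain" | calls == "amplification"] <- 1L
  num[calls == "loss"] <- -1L
  countOf <- function(m) pmax(rowSums(m == 1L), rowSums(m == -1L))
  obs <- countOf(num)
  n <- nrow(num)
  exceed <- integer(n)
  for (p in seq_len(n_perm)) {
    shifted <- vapply(seq_len(ncol(num)), function(j) {
      k <- sample.int(n, 1L)
      num[((seq_len(n) - 1L + k) %% n) + 1L, j]
    }, integer(n))
    exceed <- exceed + (countOf(shifted) >= obs)
  }
  pval <- (1 + exceed) / (n_perm + 1)
  qval <- stats::p.adjust(pval, "BH")
  gains <- rowSums(num == 1L)
  losses <- rowSums(num == -1L)
  direction <- ifelse(gains >= losses, "gain", "loss")
  flagged <- obs >= min_recurrence & qval <= fdr
  genes <- data.frame(gene_id = rownames(calls), count = obs,
                      direction = direction, p = pval, q = qval,
                      flagged = flagged, row.names = NULL,
                      stringsAsFactors = FALSE)
  chrom <- as.character(GenomicRanges::seqnames(annotation))
  grp <- cumsum(!flagged |
                  c(TRUE, chrom[-1] != chrom[-n] |
                      direction[-1] != direction[-n]))
  regions <- do.call(rbind, lapply(split(which(flagged), grp[flagged]),
                                   function(i) data.frame(
    chrom = chrom[i[1]],
    start = GenomicRanges::start(annotation)[i[1]],
    end = GenomicRanges::end(annotation)[i[length(i)]],
    n_genes = length(i), direction = direction[i[1]],
    stringsAsFactors = FALSE)))
  rownames(regions) <- NULL
  list(genes = genes, regions = regions)
}

#' Segment, re-center and call a full multi-sample probe matrix
#'
#' Convenience wrapper running [segmentProfile()] per sample and
#' chromosome, [recenterProfile()] per sample and [callSegments()], and
#' assembling called segments into a `GRanges` compatible with
#' [geneCalls()] and [writeSeg()].
#'
#' @param probes genes x samples log-ratio matrix (one probe per gene).
#' @param annotation gene `GRanges` aligned to `probes` rows.
#' @param config a [simConfig()] configuration (segmentation, centering
#'   and calling tunables are read from it).
#' @return `GRanges` of called segments with `sample`, `seg_mean`,
#'   `n_probes`, `call`.
#' @export
segmentAndCall <- function(probes, annotation, config = simConfig()) {
  chrom <- as.character(GenomicRanges::seqnames(annotation))
  pos <- GenomicRanges::start(annotation)
  out <- list()
  for (si in seq_len(ncol(probes))) {
    s <- colnames(probes)[si]
    segs <- list()
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      sp <- segmentProfile(pos[i], probes[i, si],
                           alpha = config$seg_alpha,
                           min_probes = config$seg_min_probes,
                           n_perm = config$seg_n_perm,
                           seed = deriveSeed(config$seed,
                                             1000L + si * 50L + match(ch, unique(chrom))),
                           smooth_window = config$smooth_window,
                           smooth_k = config$smooth_k)
      sp$chrom <- ch
      sp$end <- GenomicRanges::end(annotation)[i][sp$end_index]
      segs[[ch]] <- sp
    }
    segs <- do.call(rbind, segs)
    segs <- recenterProfile(segs, bw = config$recenter_bw)
    segs <- callSegments(segs, t_loss = config$t_loss,
                         t_gain = config$t_gain, t_amp = config$t_amp)
    gr <- GenomicRanges::GRanges(segs$chrom,
                                 IRanges::IRanges(segs$start, segs$end))
    gr$sample <- s
    gr$seg_mean <- segs$mean
    gr$n_probes <- segs$n_probes
    gr$call <- segs$call
    out[[s]] <- gr
  }
  sort(suppressWarnings(do.call(c, unname(out))), ignore.strand = TRUE)
}
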
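#' Per-line, per-family summed linear-scale signals
#'
#' For each line and level the member log2 values are de-logged (2^x) and
#' summed within each family; the across-line mean per family is also
#' reported. Families with no measured member are omitted with a warning.
#' The sum is permutation-invariant in member order and additive in
#' members.
#'
#' @param pe a [PairedExpression-class].
#' @param family_map named character vector `gene_id -> family` (e.g.
#'   histone family labels from the annotation `family` column).
#' @return list: `sums` (long data.frame sample x family x level with the
#'   linear `sum`), `family_means` (across-line mean per family and
#'   level).
#' @export
familySignals <- function(pe, family_map) {
  family_map <- family_map[!is.na(family_map)]
  if (!length(family_map)) stop("family map assigns no genes")
  missing_members <- setdiff(names(family_map), rownames(pe))
  if (length(missing_members)) {
    dropped <- unique(family_map[missing_members])
    family_map <- family_map[setdiff(names(family_map), missing_members)]
    gone <- setdiff(dropped, unique(family_map))
    if (length(gone))
      warning("family with no measured member omitted: ",
              paste(gone, collapse = ", "))
  }
  levels_ <- list(transcriptome = transcriptome(pe),
                  translatome = translatome(pe))
  rows <- list()
  for (lv in names(levels_)) {
    m <- 2^levels_[[lv]][names(family_map), , drop = FALSE]
    for (f in unique(family_map)) {
      s <- colSums(m[family_map == f, , drop = FALSE], na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = colnames(m), family = f, level = lv, sum = unname(s),
        stringsAsFactors = FALSE)
    }
  }
  sums <- do.call(rbind, rows)
  family_means <- stats::aggregate(sum ~ family + level, sums, mean)
  list(sums = sums, family_means = family_means)
}

#' Stoichiometry coordination: CV across families, per line and level
#'
#' The coordination metric is the coefficient of variation (sample SD /
#' mean) of the family sums across families, per line and level. A
#' coordination ratio `CV_TC / CV_TL` above 1 means the translatome
#' family levels are tighter than the transcriptome's — translational
#' restoration of stoichiometry. Per-line ratios are reported so
#' uncoordinated outlier lines are visible.
#'
#' @param family_table output of [familySignals()].
#' @return data.frame per line: `cv_tc`, `cv_tl`, `ratio`.
#' @export
stoichiometryCv <- function(family_table) {
  sums <- family_table$sums
  if (length(unique(sums$family)) < 2L)
    stop("CV needs at least 2 families")
  cv <- function(x) {
    if (mean(x) == 0) {
      message("zero mean family sum; CV undefined")
      return(NA_real_)
    }
    stats::sd(x) / mean(x)
  }
  samples <- unique(sums$sample)
  out <- do.call(rbind, lapply(samples, function(s) {
    tc <- sums$sum[sums$sample == s & sums$level == "transcriptome"]
    tl <- sums$sum[sums$sample == s & sums$level == "translatome"]
    data.frame(sample = s, cv_tc = cv(tc), cv_tl = cv(tl),
               stringsAsFactors = FALSE)
  }))
  out$ratio <- out$cv_tc / out$cv_tl
  out
}

#' Complex membership of a gene set
#'
#' `n_members` counts the set's genes belonging to at least one complex;
#' `n_complexes_half_covered` counts complexes having at least half of
#' their members in the set (exactly half counts). Catalog members
#' outside the universe are warned about and dropped.
#'
#' @param gene_set gene ids (e.g. the differentially represented set).
#' @param catalog named list of complexes (member gene-id vectors).
#' @param universe gene universe.
#' @return list: `n_members`, `frac_members`, `n_complexes_half_covered`,
#'   `frac_complexes_half_covered`, `n_complexes`.
#' @export
complexMembershipStats <- function(gene_set, catalog, universe) {
  if (!length(catalog)) stop("empty complex catalog")
  stray <- setdiff(unique(unlist(catalog)), universe)
  if (length(stray)) {
    warning(length(stray), " catalog member(s) outside universe dropped")
    catalog <- lapply(catalog, intersect, universe)
    catalog <- catalog[lengths(catalog) >= 2L]
  }
  gene_set <- intersect(gene_set, universe)
  complexed <- unique(unlist(catalog))
  n_members <- length(intersect(gene_set, complexed))
  half <- vapply(catalog, function(members)
    length(intersect(members, gene_set)) >= length(members) / 2, TRUE)
  list(n_members = n_members,
       frac_members = if (length(gene_set))
         n_members / length(gene_set) else NA_real_,
       n_complexes_half_covered = sum(half),
       frac_complexes_half_covered = sum(half) / length(catalog),
       n_complexes = length(catalog))
}

#' Bootstrap null for complex membership
#'
#' Draws `n_boot` random gene sets of the same size from the universe,
#' recomputes the `n_members` statistic on each, and reports the add-one
#' empirical p for the observed count.
#'
#' @inheritParams complexMembershipStats
#' @param n_boot bootstrap draws (>= 1).
#' @param seed integer seed.
#' @return list: `observed`, `null`, `p`.
#' @export
complexBootstrap <- function(gene_set, catalog, universe, n_boot = 1000L,
                             seed = 1L) {
  if (n_boot < 1L) stop("n_boot must be at least 1")
  if (length(universe) < length(gene_set))
    stop("universe smaller than the gene set")
  set.seed(seed)
  gene_set <- intersect(gene_set, universe)
  complexed <- intersect(unique(unlist(catalog)), universe)
  observed <- length(intersect(gene_set, complexed))
  null <- vapply(seq_len(n_boot), function(i)
    sum(sample(universe, length(gene_set)) %in% complexed), 0L)
  list(observed = observed, null = null,
       p = empiricalP(null, observed))
}
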
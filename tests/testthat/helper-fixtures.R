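# Shared fixtures and independent oracles, built in code at test time.

# A scaled-down study configuration for fast end-to-end checks.
tinyConfig <- function(seed = 42L, ...) {
  base <- list(seed = seed, n_genes = 400L, n_chrom = 4L,
               n_restore_up = 12L, n_restore_down = 12L,
               n_enhance_up = 8L, n_enhance_down = 8L,
               histone_families = c(H2A = 4L, H2B = 4L, H3 = 3L, H4 = 3L),
               region_genes = 12L, genes_per_region = 6L,
               amp_region_genes = 5L,
               seg_n_perm = 100L, rp_n_perm = 200L, sam_n_perm = 40L,
               recurrence_n_perm = 60L, n_boot = 200L,
               n_complexes = 40L, cohort_n = 100L)
  do.call(simConfig, utils::modifyList(base, list(...)))
}

# small paired-expression object with exactly known values
makePE <- function(tc, tl = tc) {
  g <- paste0("g", seq_len(nrow(tc)))
  s <- paste0("S", seq_len(ncol(tc)))
  dimnames(tc) <- dimnames(tl) <- list(g, s)
  PairedExpression(tc, tl)
}

# Exhaustive rank-product oracle: enumerates every equiprobable
# assignment of per-sample rank vectors ((G!)^S configurations) and
# computes the exact expected false-positive count and PFP. Independent
# of the package's permutation implementation.
allPermutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(allPermutations(v[-i]), function(p) c(v[i], p))))
}

rpOracle <- function(fc, direction = "up") {
  g <- nrow(fc); s <- ncol(fc)
  sgn <- if (direction == "up") -1 else 1
  obs_log <- rowMeans(log(apply(sgn * fc, 2, rank)))
  perms <- allPermutations(seq_len(g))
  grid <- expand.grid(rep(list(seq_along(perms)), s))
  null_log <- apply(grid, 1, function(row) {
    rowMeans(log(vapply(row, function(k) perms[[k]], integer(g))))
  })  # g x n_config
  e_fp <- vapply(obs_log, function(r) mean(colSums(null_log <= r + 1e-9)),
                 0)
  pos <- rank(exp(obs_log), ties.method = "max")
  list(rp = exp(obs_log), e_fp = e_fp, pfp = pmin(e_fp / pos, 1))
}

# Hand log-rank oracle: O - E and hypergeometric variance summed over
# distinct event times, two groups, no approximations.
logrankOracle <- function(timeA, eventA, timeB, eventB) {
  time <- c(timeA, timeB); event <- c(eventA, eventB)
  grp <- rep(c(0, 1), c(length(timeA), length(timeB)))
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE),
       obs_minus_exp = o_minus_e)
}
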
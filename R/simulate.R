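#' Simulation / run configuration
#'
#' One declarative configuration object carrying every tunable of the
#' generator and of the downstream analysis stages, including all seeds.
#' Serializing with [writeConfig()] and reloading with [readConfig()]
#' yields an identical configuration.
#'
#' The generator emulates the study design the package targets: a panel of
#' 13 cell lines profiled at the transcriptome and translatome levels,
#' carrying recurrent segmental copy-number alterations. Copy state is an
#' integer offset from neutral (-1 loss, +1 gain, +2 amplification);
#' transcription responds linearly to dosage
#' (`TC = mu + dosage_effect * state + noise`) and the translatome adds a
#' compensation term `delta = -compensation * dosage_effect * state` for
#' RESTORE genes (`+` for ENHANCE), so at `compensation = 1` a planted
#' RESTORE gene is fully buffered. Replication-dependent histone families
#' get dispersed transcriptome family sums but translatome member levels
#' rescaled per line so each family's linear-scale sum hits a fixed
#' stoichiometric target; one control line (`histone_control_line`) skips
#' the rescaling and so mimics a line lacking the coordination machinery.
#' RESTORE-class lesions are made more recurrent than ENHANCE-class
#' lesions (`recurrence_restore` vs `recurrence_enhance`), encoding the
#' premise that compensated alterations are tolerated and fixed more
#' often than magnifying ones.
#'
#' @param seed master integer seed; every stochastic stage derives its own
#'   stream from it.
#' @param n_genes,n_chrom,n_lines genome and panel size.
#' @param n_restore_up,n_restore_down,n_enhance_up,n_enhance_down planted
#'   class counts.
#' @param histone_families named integer vector, members per family.
#' @param dosage_effect log2 units of transcriptome shift per copy-state
#'   step (beta).
#' @param compensation fraction in \[0, 1\] of the dosage term undone
#'   (RESTORE) or doubled (ENHANCE) at the translatome (gamma).
#' @param noise_sd per-cell expression noise, log2 units (sigma).
#' @param probe_noise_sd aCGH probe noise around the segment mean.
#' @param region_genes,genes_per_region genes spanned by a recurrent
#'   region and how many of them carry the planted class.
#' @param recurrence_restore,recurrence_enhance lines altered per region.
#' @param amp_region_genes size of the single amplicon planted in all
#'   lines (an MYCN-like high-level gain, no planted TE effect).
#' @param state_logratio expected segment log2 ratio per call state.
#' @param baseline_mean,baseline_sd distribution of gene baselines mu_g.
#' @param planted_min_quantile planted-class genes draw their baselines
#'   above this quantile of the baseline distribution (compensation is
#'   only observable on expressed genes).
#' @param histone_tc_spread log2 SD of the per-line, per-family
#'   transcriptome dispersion the translatome must undo.
#' @param histone_sum_noise residual log2 noise on coordinated histone
#'   translatome levels.
#' @param histone_control_line line index with coordination disabled.
#' @param n_program,program_sd a shared translational program: this many
#'   CNA-free, non-histone genes get a per-gene translatome offset
#'   (`Normal(0, program_sd)` log2 units) common to all lines, emulating
#'   the genome-wide translational regulation shared across the panel
#'   that makes translatome profiles cluster together.
#' @param cohort_n,baseline_hazard,hazard_ratio,prognostic_fraction,censor_rate
#'   survival cohort: size, exponential baseline hazard, hazard ratio of
#'   the adverse group, fraction of RESTORE genes made prognostic, and
#'   independent censoring probability per patient.
#' @param n_complexes,complex_size,complex_weight protein-complex catalog:
#'   count, size range, and sampling weight favouring differentially
#'   represented genes.
#' @param n_tumor_types,concordance,background_freq pan-cancer table:
#'   tumor-type count, fraction of the concordant-alteration signal
#'   planted for RESTORE genes (1 gives frequency exactly 1), and the
#'   upper bound of background alteration frequencies.
#' @param category_props fraction of genes tagged with each category.
#' @param seg_alpha,seg_min_probes,seg_n_perm,smooth_k,smooth_window
#'   segmentation tunables (see [segmentProfile()]).
#' @param recenter_bw kernel bandwidth for [recenterProfile()].
#' @param t_loss,t_gain,t_amp calling thresholds (see [callSegments()]).
#' @param min_recurrence,recurrence_n_perm,recurrence_fdr recurrent
#'   aberration test tunables.
#' @param rp_n_perm,pfp_threshold rank-product permutations and PFP cut.
#' @param q_threshold BH q cut for the paired t-test.
#' @param sam_n_perm,sam_bins,sam_fdr SAM tunables.
#' @param detect_quartile_type quantile convention for detectability
#'   (R type 7, linear interpolation; pinned so tests are exact).
#' @param n_boot bootstrap draws for the pan-cancer and complex nulls.
#' @param kmeans_k,kmeans_nstart profile clustering tunables.
#' @param prognosis_alpha per-gene log-rank significance level.
#' @param provenance free-text note carried into serialized outputs.
#'
#' @return a validated configuration list of class `restoreConfig`.
#' @export
simConfig <- function(seed = 1L,
                      n_genes = 2000L, n_chrom = 6L, n_lines = 13L,
                      n_restore_up = 60L, n_restore_down = 60L,
                      n_enhance_up = 40L, n_enhance_down = 40L,
                      histone_families = c(H1 = 3L, H2A = 12L, H2B = 16L,
                                           H3 = 5L, H4 = 9L),
                      dosage_effect = 1, compensation = 1, noise_sd = 0.25,
                      probe_noise_sd = 0.15,
                      region_genes = 25L, genes_per_region = 20L,
                      recurrence_restore = 9L, recurrence_enhance = 6L,
                      amp_region_genes = 10L,
                      state_logratio = c(loss = -1, neutral = 0,
                                         gain = 0.58, amplification = 2),
                      baseline_mean = 8, baseline_sd = 1.5,
                      planted_min_quantile = 0.35,
                      histone_tc_spread = 0.75, histone_sum_noise = 0.02,
                      histone_control_line = 5L,
                      n_program = 250L, program_sd = 1.0,
                      cohort_n = 200L, baseline_hazard = 0.1,
                      hazard_ratio = 3.5, prognostic_fraction = 0.65,
                      censor_rate = 0.2,
                      n_complexes = 120L, complex_size = c(2L, 6L),
                      complex_weight = 4,
                      n_tumor_types = 27L, concordance = 0.8,
                      background_freq = 0.3,
                      category_props = c(RBP = 0.10, miRNA = 0.05,
                                         TF = 0.08, kinase = 0.06,
                                         proliferation = 0.05,
                                         differentiation = 0.05),
                      seg_alpha = 0.01, seg_min_probes = 5L,
                      seg_n_perm = 100L, smooth_k = 4, smooth_window = 5L,
                      recenter_bw = 0.1,
                      t_loss = 0.2, t_gain = 0.2, t_amp = 1.0,
                      min_recurrence = 5L, recurrence_n_perm = 200L,
                      recurrence_fdr = 0.05,
                      rp_n_perm = 1000L, pfp_threshold = 0.05,
                      q_threshold = 0.05,
                      sam_n_perm = 200L, sam_bins = 10L, sam_fdr = 0.05,
                      detect_quartile_type = 7L,
                      n_boot = 1000L,
                      kmeans_k = 3L, kmeans_nstart = 20L,
                      prognosis_alpha = 0.05,
                      provenance = "restoreTE synthetic study") {
  config <- as.list(environment())
  n_planted <- n_restore_up + n_restore_down + n_enhance_up + n_enhance_down
  if (n_planted + sum(histone_families) > n_genes)
    stop("planted class counts plus histone genes exceed n_genes")
  if (compensation < 0 || compensation > 1)
    stop("compensation must lie in [0, 1]")
  if (noise_sd < 0 || probe_noise_sd < 0)
    stop("noise SDs must be non-negative")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (t_gain >= t_amp) stop("thresholds must satisfy t_gain < t_amp")
  if (genes_per_region > region_genes)
    stop("genes_per_region cannot exceed region_genes")
  if (histone_control_line < 1 || histone_control_line > n_lines)
    stop("histone_control_line out of range")
  class(config) <- "restoreConfig"
  config
}

restoreClasses <- c("RESTORE_UP", "RESTORE_DOWN", "ENHANCE_UP",
                    "ENHANCE_DOWN")

#' Simulate a gene annotation catalog
#'
#' Genes tile `n_chrom` chromosomes without overlap (5 kb genes on a 10 kb
#' grid). Category tags are assigned independently per gene at the
#' configured proportions. Histone-family members are placed as a
#' contiguous cluster at the head of the last chromosome (which is kept
#' free of copy-number regions), mirroring the clustered organisation of
#' replication-dependent histone genes.
#'
#' @param config a [simConfig()] configuration.
#' @return `GRanges` with `gene_id`, `symbol`, `categories`, `family`.
#' @export
simulateAnnotation <- function(config = simConfig()) {
  set.seed(deriveSeed(config$seed, 1L))
  n <- config$n_genes
  per_chrom <- diff(round(seq(0, n, length.out = config$n_chrom + 1L)))
  chrom <- rep(paste0("chr", seq_len(config$n_chrom)), per_chrom)
  within <- unlist(lapply(per_chrom, seq_len))
  start <- (within - 1L) * 10000L + 1L
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + 4999L),
                               strand = "*")
  gr$gene_id <- sprintf("g%04d", seq_len(n))
  gr$symbol <- sprintf("GENE%d", seq_len(n))
  cats <- lapply(seq_len(n), function(i) character(0))
  for (tag in names(config$category_props)) {
    hit <- which(stats::runif(n) < config$category_props[[tag]])
    for (i in hit) cats[[i]] <- c(cats[[i]], tag)
  }
  fam <- rep(NA_character_, n)
  hf <- config$histone_families
  if (sum(hf) > 0) {
    first_last <- n - per_chrom[config$n_chrom] + 1L
    idx <- first_last:(first_last + sum(hf) - 1L)
    fam[idx] <- rep(names(hf), hf)
    for (i in idx) cats[[i]] <- unique(c(cats[[i]], "histone"))
  }
  gr$categories <- IRanges::CharacterList(cats)
  gr$family <- fam
  names(gr) <- gr$gene_id
  gr
}

# Deterministic line-incidence pattern: k regions of one class rotate a
# window of `recurrence` lines around the panel so every line is covered
# by at least one region when k * recurrence >= n_lines.
regionLines <- function(j, k, recurrence, n_lines) {
  offset <- (j - 1L) * max(1L, floor(n_lines / k))
  sort(((offset + 0:(recurrence - 1L)) %% n_lines) + 1L)
}

#' Simulate recurrent copy-number alterations
#'
#' Plants class-specific recurrent segmental regions (losses hosting
#' RESTORE_UP / ENHANCE_DOWN genes, gains hosting RESTORE_DOWN /
#' ENHANCE_UP genes, plus one pan-panel amplicon), then emits per-line
#' probe log-ratios equal to the planted segment mean plus
#' `Normal(0, probe_noise_sd)`, one probe per gene at the gene midpoint.
#'
#' @param annotation from [simulateAnnotation()].
#' @param config a [simConfig()] configuration.
#' @return list with `states` (genes x lines integer copy-state offsets),
#'   `probes` (genes x lines log-ratio matrix), `segments` (true segment
#'   `GRanges` with calls), `classes` (planted class per gene, `"NONE"`
#'   where unplanted), and `regions` (per-region metadata).
#' @export
simulateCna <- function(annotation, config = simConfig()) {
  set.seed(deriveSeed(config$seed, 2L))
  n <- length(annotation)
  lines <- sprintf("L%02d", seq_len(config$n_lines))
  chroms <- paste0("chr", seq_len(config$n_chrom - 1L))  # last chrom free
  chrom_of <- as.character(GenomicRanges::seqnames(annotation))

  plan <- list(
    RESTORE_UP = list(n = config$n_restore_up, dir = -1L,
                      rec = config$recurrence_restore),
    RESTORE_DOWN = list(n = config$n_restore_down, dir = 1L,
                        rec = config$recurrence_restore),
    ENHANCE_UP = list(n = config$n_enhance_up, dir = 1L,
                      rec = config$recurrence_enhance),
    ENHANCE_DOWN = list(n = config$n_enhance_down, dir = -1L,
                        rec = config$recurrence_enhance))
  regions <- list()
  for (cls in names(plan)) {
    p <- plan[[cls]]
    if (p$n == 0) next
    k <- ceiling(p$n / config$genes_per_region)
    left <- p$n
    for (j in seq_len(k)) {
      regions[[length(regions) + 1L]] <- list(
        class = cls, dir = p$dir, state = p$dir,
        n_planted = min(config$genes_per_region, left),
        width = config$region_genes,
        lines = regionLines(j, k, p$rec, config$n_lines))
      left <- left - config$genes_per_region
    }
  }
  if (config$amp_region_genes > 0)
    regions[[length(regions) + 1L]] <- list(
      class = "NONE", dir = 1L, state = 2L, n_planted = 0L,
      width = config$amp_region_genes, lines = seq_len(config$n_lines))

  # place regions round-robin over the CNA-eligible chromosomes
  assigned <- split(seq_along(regions),
                    rep_len(seq_along(chroms), length(regions)))
  placement <- vector("list", length(regions))
  for (ci in seq_along(chroms)) {
    ids <- assigned[[as.character(ci)]]
    if (is.null(ids)) next
    gidx <- which(chrom_of == chroms[ci])
    slot <- floor(length(gidx) / length(ids))
    margin <- 5L  # keep region edges >= min_probes away from slot ends
    for (r in seq_along(ids)) {
      w <- regions[[ids[r]]]$width
      if (slot - w - 2L * margin < 1L)
        stop("region width exceeds chromosome capacity on ", chroms[ci])
      jitter <- margin + sample.int(slot - w - 2L * margin, 1L)
      first <- gidx[(r - 1L) * slot + jitter]
      placement[[ids[r]]] <- first:(first + w - 1L)
    }
  }

  states <- matrix(0L, n, config$n_lines,
                   dimnames = list(annotation$gene_id, lines))
  classes <- rep("NONE", n)
  names(classes) <- annotation$gene_id
  for (r in seq_along(regions)) {
    reg <- regions[[r]]
    idx <- placement[[r]]
    states[idx, reg$lines] <- reg$state
    if (reg$n_planted > 0) {
      planted <- sort(sample(idx, reg$n_planted))
      classes[planted] <- reg$class
      regions[[r]]$planted <- annotation$gene_id[planted]
    }
    regions[[r]]$genes <- annotation$gene_id[idx]
  }

  lr <- config$state_logratio
  state_lr <- matrix(lr[c("loss", "neutral", "gain", "amplification")][
    match(states, c(-1L, 0L, 1L, 2L))], n, config$n_lines,
    dimnames = dimnames(states))
  probes <- state_lr + stats::rnorm(length(state_lr),
                                    sd = config$probe_noise_sd)

  segments <- trueSegments(annotation, states, state_lr)
  list(states = states, probes = probes, segments = segments,
       classes = classes, regions = regions)
}

# collapse per-gene states into true segment GRanges per line
trueSegments <- function(annotation, states, state_lr) {
  chrom_of <- as.character(GenomicRanges::seqnames(annotation))
  out <- list()
  for (s in colnames(states)) {
    for (ch in unique(chrom_of)) {
      i <- which(chrom_of == ch)
      r <- rle(states[i, s])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      gr <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(GenomicRanges::start(annotation)[i[starts]],
                             GenomicRanges::end(annotation)[i[ends]]))
      gr$sample <- s
      gr$seg_mean <- state_lr[i[starts], s]
      gr$n_probes <- r$lengths
      gr$call <- c("loss", "neutral", "gain",
                   "amplification")[match(r$values, c(-1L, 0L, 1L, 2L))]
      out[[length(out) + 1L]] <- gr
    }
  }
  sort(suppressWarnings(do.call(c, out)), ignore.strand = TRUE)
}

#' Simulate paired transcriptome/translatome expression
#'
#' Implements the dosage-plus-compensation model described in
#' [simConfig()]: `TC = mu + beta * state + eps`;
#' `TL = TC + delta + eps'` with `delta = -gamma * beta * state` for
#' RESTORE genes and `+gamma * beta * state` for ENHANCE genes. Histone
#' family members get a per-line, per-family transcriptome dispersion
#' which the translatome undoes by rescaling member levels so the
#' family's linear-scale sum equals its stoichiometric target (except in
#' the control line).
#'
#' @param annotation from [simulateAnnotation()].
#' @param cna from [simulateCna()]; its `states` must cover all genes.
#' @param config a [simConfig()] configuration.
#' @return list with `pe` (a [PairedExpression-class]) and `truth` (planted
#'   classes, copy states, histone family targets, control line).
#' @export
simulateExpression <- function(annotation, cna, config = simConfig()) {
  set.seed(deriveSeed(config$seed, 3L))
  states <- cna$states
  if (!identical(rownames(states), annotation$gene_id))
    stop("copy-state matrix does not cover the annotation genes")
  n <- nrow(states)
  n_lines <- ncol(states)
  mu <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  names(mu) <- rownames(states)
  # compensation classes are planted on expressed genes: translational
  # buffering of dosage is only defined for transcripts the cell both
  # expresses and is sensitive to, so their baselines are drawn from the
  # upper (1 - planted_min_quantile) of the baseline distribution
  is_planted <- cna$classes != "NONE"
  if (any(is_planted)) {
    u <- stats::runif(sum(is_planted), config$planted_min_quantile, 1)
    mu[is_planted] <- stats::qnorm(u, config$baseline_mean,
                                   config$baseline_sd)
  }
  beta <- config$dosage_effect
  gamma <- config$compensation

  tc <- mu + beta * states +
    stats::rnorm(length(states), sd = config$noise_sd)
  delta <- matrix(0, n, n_lines)
  restore <- cna$classes %in% c("RESTORE_UP", "RESTORE_DOWN")
  enhance <- cna$classes %in% c("ENHANCE_UP", "ENHANCE_DOWN")
  delta[restore, ] <- -gamma * beta * states[restore, ]
  delta[enhance, ] <- gamma * beta * states[enhance, ]
  # shared translational program: CNA-free, non-histone genes regulated
  # identically across the panel (indirect targets of the same trans
  # factors), the bulk of the differentially represented set
  program <- numeric(0)
  eligible <- which(cna$classes == "NONE" & is.na(annotation$family) &
                      rowSums(states != 0L) == 0L)
  n_prog <- min(config$n_program, length(eligible))
  if (n_prog > 0) {
    idx <- sort(sample(eligible, n_prog))
    program <- stats::setNames(stats::rnorm(n_prog, sd = config$program_sd),
                               rownames(states)[idx])
    delta[idx, ] <- delta[idx, ] + program
  }
  tl <- tc + delta + stats::rnorm(length(states), sd = config$noise_sd)
  dimnames(tc) <- dimnames(tl) <- dimnames(states)

  fam <- annotation$family
  targets <- NULL
  if (any(!is.na(fam))) {
    ctrl <- config$histone_control_line
    # coordination target: every family converges to one common
    # nucleosome-equivalent level (geometric mean of the baseline sums)
    raw_sums <- vapply(split(2^mu[!is.na(fam)], fam[!is.na(fam)]), sum, 0)
    targets <- stats::setNames(rep(exp(mean(log(raw_sums))),
                                   length(raw_sums)), names(raw_sums))
    for (f in unique(fam[!is.na(fam)])) {
      i <- which(!is.na(fam) & fam == f)
      spread <- stats::rnorm(n_lines, sd = config$histone_tc_spread)
      tc[i, ] <- mu[i] + rep(spread, each = length(i)) +
        stats::rnorm(length(i) * n_lines, sd = config$noise_sd)
      for (l in seq_len(n_lines)) {
        if (l == ctrl) {
          tl[i, l] <- tc[i, l] + stats::rnorm(length(i),
                                              sd = config$noise_sd)
        } else {
          shift <- log2(targets[[f]] / sum(2^tc[i, l]))
          tl[i, l] <- tc[i, l] + shift +
            stats::rnorm(length(i), sd = config$histone_sum_noise)
        }
      }
    }
  }

  pe <- PairedExpression(tc, tl, rowRanges = annotation)
  truth <- list(classes = cna$classes, states = states,
                family_targets = targets,
                histone_control_line = config$histone_control_line,
                baselines = mu, program = program)
  list(pe = pe, truth = truth)
}

#' Simulate a survival cohort with planted prognostic RESTORE genes
#'
#' Patients carry a latent adverse indicator (probability 1/2). Event
#' times are exponential with the baseline hazard multiplied by the
#' configured hazard ratio for adverse patients; censoring is independent
#' (each patient is censored with probability `censor_rate` at a uniform
#' fraction of its event time). A configured fraction of RESTORE genes is
#' prognostic: their cohort expression tracks the adverse group in the
#' direction that matches the compensation class (high expression adverse
#' for RESTORE_DOWN, low for RESTORE_UP); the rest are independent noise.
#'
#' @param truth ground truth from [simulateExpression()].
#' @param config a [simConfig()] configuration.
#' @return list with `time`, `event`, `expr` (genes x patients),
#'   `prognostic` gene ids and the latent `adverse` indicator.
#' @export
simulateCohort <- function(truth, config = simConfig()) {
  if (config$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  set.seed(deriveSeed(config$seed, 4L))
  genes <- names(truth$classes)
  restore_genes <- genes[truth$classes %in% c("RESTORE_UP",
                                              "RESTORE_DOWN")]
  n <- config$cohort_n
  adverse <- stats::rbinom(n, 1L, 0.5)
  n_prog <- round(config$prognostic_fraction * length(restore_genes))
  prognostic <- sort(sample(restore_genes, n_prog))
  expr <- matrix(stats::rnorm(length(genes) * n, sd = 0.75),
                 length(genes), n,
                 dimnames = list(genes, sprintf("P%03d", seq_len(n))))
  for (g in prognostic) {
    sgn <- if (truth$classes[[g]] == "RESTORE_DOWN") 1 else -1
    expr[g, ] <- sgn * adverse + stats::rnorm(n, sd = 0.5)
  }
  rate <- config$baseline_hazard * config$hazard_ratio^adverse
  t_event <- stats::rexp(n, rate)
  censored <- stats::runif(n) < config$censor_rate
  time <- ifelse(censored, t_event * stats::runif(n), t_event)
  event <- as.integer(!censored)
  names(time) <- names(event) <- colnames(expr)
  list(time = time, event = event, expr = expr,
       prognostic = prognostic, adverse = adverse)
}

#' Simulate annotation catalogs: complexes, pan-cancer frequencies,
#' category tables
#'
#' The protein-complex catalog samples members with a weight favouring
#' the planted differentially represented genes (classes plus histones),
#' so complex membership of the diffrep set is genuinely enriched. The
#' pan-cancer table mixes a background alteration frequency with a
#' planted concordant component for RESTORE genes: at `concordance = 1`
#' a RESTORE_DOWN gene has gain frequency exactly 1 in every tumor type.
#'
#' @param annotation from [simulateAnnotation()].
#' @param truth ground truth from [simulateExpression()].
#' @param config a [simConfig()] configuration.
#' @return list with `complexes` (named list of gene-id vectors),
#'   `freq_table` (long data.frame: gene_id, tumor_type, gain_freq,
#'   loss_freq) and `categories` (named list of gene sets from the
#'   annotation tags).
#' @export
simulateCatalogs <- function(annotation, truth, config = simConfig()) {
  if (config$complex_size[1] < 2) stop("complex size must be at least 2")
  set.seed(deriveSeed(config$seed, 5L))
  genes <- annotation$gene_id
  planted <- truth$classes != "NONE" | !is.na(annotation$family) |
    genes %in% names(truth$program)
  w <- ifelse(planted, config$complex_weight, 1)
  sizes <- sample(seq(config$complex_size[1], config$complex_size[2]),
                  config$n_complexes, replace = TRUE)
  complexes <- lapply(sizes, function(k) sample(genes, k, prob = w))
  names(complexes) <- sprintf("C%03d", seq_along(complexes))

  types <- sprintf("T%02d", seq_len(config$n_tumor_types))
  nn <- length(genes) * length(types)
  bg_gain <- stats::runif(nn, 0, config$background_freq)
  bg_loss <- stats::runif(nn, 0, config$background_freq)
  tab <- data.frame(gene_id = rep(genes, times = length(types)),
                    tumor_type = rep(types, each = length(genes)),
                    gain_freq = bg_gain, loss_freq = bg_loss,
                    stringsAsFactors = FALSE)
  conc <- config$concordance
  up <- tab$gene_id %in% names(truth$classes)[truth$classes == "RESTORE_UP"]
  down <- tab$gene_id %in%
    names(truth$classes)[truth$classes == "RESTORE_DOWN"]
  tab$loss_freq[up] <- (1 - conc) * tab$loss_freq[up] + conc
  tab$gain_freq[down] <- (1 - conc) * tab$gain_freq[down] + conc

  tags <- unique(unlist(annotation$categories))
  categories <- lapply(tags, function(tg)
    genes[vapply(annotation$categories, function(x) tg %in% x, TRUE)])
  names(categories) <- tags
  list(complexes = complexes, freq_table = tab, categories = categories)
}

#' Simulate a complete study
#'
#' Runs all generators off one configuration and returns every input the
#' analysis stages consume, together with the ground truth.
#'
#' @param config a [simConfig()] configuration.
#' @return list: `annotation`, `cna`, `pe`, `truth`, `cohort`, `catalogs`,
#'   `config`.
#' @export
simulateStudy <- function(config = simConfig()) {
  annotation <- simulateAnnotation(config)
  cna <- simulateCna(annotation, config)
  expr <- simulateExpression(annotation, cna, config)
  cohort <- simulateCohort(expr$truth, config)
  catalogs <- simulateCatalogs(annotation, expr$truth, config)
  list(annotation = annotation, cna = cna, pe = expr$pe,
       truth = expr$truth, cohort = cohort, catalogs = catalogs,
       config = config)
}
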
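test_that("simulated annotation tiles chromosomes and is reproducible", {
  cfg <- tinyConfig()
  ann <- simulateAnnotation(cfg)
  expect_length(ann, cfg$n_genes)
  expect_equal(length(unique(GenomicRanges::seqnames(ann))), cfg$n_chrom)
  # no overlap within chromosomes
  expect_equal(length(GenomicRanges::findOverlaps(ann, drop.self = TRUE,
                                                  drop.redundant = TRUE)),
               0L)
  expect_identical(ann, simulateAnnotation(cfg))
  expect_equal(sum(!is.na(ann$family)), sum(cfg$histone_families))
  expect_error(simConfig(n_genes = 100L, n_restore_up = 200L),
               "exceed n_genes")
})

test_that("zero probe noise reproduces planted segment means exactly", {
  cfg <- tinyConfig(probe_noise_sd = 0)
  ann <- simulateAnnotation(cfg)
  cna <- simulateCna(ann, cfg)
  lr <- cfg$state_logratio
  expected <- matrix(lr[match(cna$states, c(-1L, 0L, 1L, 2L))],
                     nrow(cna$states))
  expect_equal(unname(cna$probes), expected)
  # all genes inside a planted loss region carry the loss state in the
  # region's lines
  loss_regions <- Filter(function(r) r$state == -1L, cna$regions)
  for (r in loss_regions)
    expect_true(all(cna$states[r$genes, r$lines] == -1L))
  expect_equal(cna$probes, simulateCna(ann, cfg)$probes)
})

test_that("expression obeys the dosage/compensation model in the noiseless limit", {
  cfg <- tinyConfig(noise_sd = 0, probe_noise_sd = 0, compensation = 1,
                    histone_families = integer(0))
  ann <- simulateAnnotation(cfg)
  cna <- simulateCna(ann, cfg)
  ex <- simulateExpression(ann, cna, cfg)
  tc <- transcriptome(ex$pe); tl <- translatome(ex$pe)
  mu <- ex$truth$baselines
  beta <- cfg$dosage_effect
  # transcription follows dosage linearly
  expect_equal(unname(tc), unname(mu + beta * cna$states))
  # full compensation: RESTORE translatome returns to baseline
  rg <- names(which(cna$classes == "RESTORE_DOWN"))
  expect_true(length(rg) > 0)
  for (g in rg) {
    gained <- cna$states[g, ] == 1L
    expect_equal(unname(tc[g, gained]), unname(mu[g] + beta)[rep(1, sum(gained))])
    expect_equal(unname(tl[g, gained]), rep(unname(mu[g]), sum(gained)))
  }
  # ENHANCE doubles the shift
  eg <- names(which(cna$classes == "ENHANCE_UP"))[1]
  gained <- cna$states[eg, ] == 1L
  expect_equal(unname(tl[eg, gained]), rep(unname(mu[eg]) + 2 * beta,
                                           sum(gained)))
  # no compensation (and no shared program): the two levels coincide
  cfg0 <- tinyConfig(noise_sd = 0, probe_noise_sd = 0, compensation = 0,
                     histone_families = integer(0), n_program = 0L)
  ann0 <- simulateAnnotation(cfg0)
  ex0 <- simulateExpression(ann0, simulateCna(ann0, cfg0), cfg0)
  expect_equal(translatome(ex0$pe), transcriptome(ex0$pe))
})

test_that("histone translatome sums hit the family target; transcriptome disperses", {
  cfg <- tinyConfig()
  ann <- simulateAnnotation(cfg)
  cna <- simulateCna(ann, cfg)
  ex <- simulateExpression(ann, cna, cfg)
  fam <- ann$family
  targets <- ex$truth$family_targets
  ctrl <- cfg$histone_control_line
  for (f in names(targets)) {
    members <- ann$gene_id[!is.na(fam) & fam == f]
    tl_sums <- colSums(2^translatome(ex$pe)[members, , drop = FALSE])
    tc_sums <- colSums(2^transcriptome(ex$pe)[members, , drop = FALSE])
    expect_true(all(abs(tl_sums[-ctrl] / targets[[f]] - 1) < 0.05))
    expect_true(max(tc_sums) / min(tc_sums) >= 2)
  }
})

test_that("cohort p-values are calibrated at null effect and powered at HR 5", {
  null_p <- vapply(1:200, function(sd_) {
    cfg <- tinyConfig(seed = sd_, hazard_ratio = 1, cohort_n = 60L,
                      n_genes = 60L, n_restore_up = 4L, n_restore_down = 4L,
                      n_enhance_up = 2L, n_enhance_down = 2L,
                      region_genes = 6L, genes_per_region = 4L,
                      histone_families = integer(0), n_chrom = 2L,
                      amp_region_genes = 0L)
    truth <- list(classes = stats::setNames(
      rep(c("RESTORE_DOWN", "NONE"), c(4, 56)), sprintf("g%04d", 1:60)))
    co <- simulateCohort(truth, cfg)
    g <- co$prognostic[1]
    x <- co$expr[g, ]; high <- x > median(x)
    logrankTest(co$time[!high], co$event[!high],
                co$time[high], co$event[high])$p
  }, 0)
  expect_gt(stats::ks.test(null_p, "punif")$p.value, 0.01)

  hits <- vapply(1:100, function(sd_) {
    cfg <- tinyConfig(seed = 1000L + sd_, hazard_ratio = 5,
                      cohort_n = 200L)
    truth <- list(classes = stats::setNames(
      rep(c("RESTORE_DOWN", "NONE"), c(10, 90)), sprintf("g%04d", 1:100)))
    co <- simulateCohort(truth, cfg)
    g <- co$prognostic[1]
    x <- co$expr[g, ]; high <- x > median(x)
    logrankTest(co$time[!high], co$event[!high],
                co$time[high], co$event[high])$p < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("fully censored cohorts propagate cleanly to the log-rank test", {
  cfg <- tinyConfig(censor_rate = 1)
  truth <- list(classes = stats::setNames(
    rep(c("RESTORE_UP", "NONE"), c(5, 95)), sprintf("g%04d", 1:100)))
  co <- simulateCohort(truth, cfg)
  expect_equal(sum(co$event), 0L)
  expect_message(
    res <- logrankTest(co$time[1:50], co$event[1:50],
                       co$time[51:100], co$event[51:100]),
    "no events")
  expect_true(is.na(res$p))
})

test_that("catalogs plant concordance and reproduce under one seed", {
  cfg <- tinyConfig(concordance = 1)
  ann <- simulateAnnotation(cfg)
  cna <- simulateCna(ann, cfg)
  ex <- simulateExpression(ann, cna, cfg)
  cats <- simulateCatalogs(ann, ex$truth, cfg)
  down <- names(which(ex$truth$classes == "RESTORE_DOWN"))
  sub <- cats$freq_table[cats$freq_table$gene_id %in% down, ]
  expect_true(all(sub$gain_freq == 1))
  expect_identical(cats$freq_table,
                   simulateCatalogs(ann, ex$truth, cfg)$freq_table)
  expect_true(all(lengths(cats$complexes) >= 2))
  expect_error(simulateCatalogs(ann, ex$truth,
                                tinyConfig(complex_size = c(1L, 3L))),
               "complex size")
})
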
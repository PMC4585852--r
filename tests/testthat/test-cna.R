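test_that("segmentation recovers exact breakpoints and respects the null", {
  pos <- seq_len(100) * 10
  # constant track: one segment with the constant mean
  seg <- segmentProfile(pos, rep(0.3, 100), seed = 1L)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$mean, 0.3)
  expect_equal(seg$n_probes, 100L)

  # noiseless step 0 -> 1 at probe 50: breakpoint exactly there
  x <- rep(c(0, 1), each = 50)
  seg <- segmentProfile(pos, x, seed = 1L)
  expect_equal(seg$end_index, c(50L, 100L))
  expect_equal(seg$mean, c(0, 1))

  # pure-noise tracks: false splits bounded near alpha
  splits <- vapply(1:100, function(i) {
    set.seed(i)
    nrow(segmentProfile(pos, rnorm(100), alpha = 0.01, n_perm = 60L,
                        seed = 1000L + i)) > 1
  }, TRUE)
  expect_lte(mean(splits), 0.05)
})

test_that("segmentation is invariant to adding a constant to the track", {
  pos <- seq_len(120)
  set.seed(3)
  x <- rnorm(120, mean = rep(c(0, 0.8, 0), c(40, 40, 40)), sd = 0.2)
  a <- segmentProfile(pos, x, seed = 5L)
  b <- segmentProfile(pos, x + 2.5, seed = 5L)
  expect_equal(a$end_index, b$end_index)
  expect_equal(b$mean, a$mean + 2.5)
})

test_that("re-centering shifts by the probe-weighted density mode", {
  segs <- data.frame(mean = c(0.3, 0.3, 1.2, -0.6),
                     n_probes = c(500L, 400L, 30L, 20L))
  out <- recenterProfile(segs, bw = 0.1)
  expect_equal(attr(out, "shift"), 0.3, tolerance = 0.02)
  expect_equal(out$mean[1], 0, tolerance = 0.02)

  one <- recenterProfile(data.frame(mean = 0.7, n_probes = 10L))
  expect_equal(one$mean, 0)

  centered <- data.frame(mean = c(-0.05, 0.02, 0.01, 1.5),
                         n_probes = c(300L, 300L, 300L, 10L))
  out <- recenterProfile(centered, bw = 0.1)
  expect_lt(abs(attr(out, "shift")), 0.05)
})

test_that("threshold calling maps means to states per the defaults", {
  segs <- data.frame(mean = c(-0.5, 1.5, 0, 0.3, -0.15))
  out <- callSegments(segs)
  expect_equal(out$call,
               c("loss", "amplification", "neutral", "gain", "neutral"))
  expect_error(callSegments(segs, t_gain = 1, t_amp = 0.5),
               "t_gain < t_amp")
})

test_that("gene direction consensus follows the sign-unanimity rule", {
  calls <- rbind(
    gA = c("gain", "gain", rep("neutral", 11)),
    gB = c("gain", "loss", rep("neutral", 11)),
    gC = rep("neutral", 13),
    gD = c("amplification", "gain", "gain", rep("neutral", 10)))
  out <- assignGeneDirection(calls)
  expect_equal(out$direction, c("gain", "conflict", "none", "gain"))
  expect_equal(out$support, c(2, 1, 0, 3))
})

test_that("recurrence scoring flags concordant genes and merges regions", {
  ann <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges((0:19) * 100 + 1,
                                                 (0:19) * 100 + 90))
  ann$gene_id <- sprintf("g%02d", 1:20)
  names(ann) <- ann$gene_id
  calls <- matrix("neutral", 20, 13,
                  dimnames = list(ann$gene_id, sprintf("L%02d", 1:13)))
  calls[5:10, ] <- "gain"  # six adjacent genes gained in all 13 lines
  res <- recurrentAberrations(calls, ann, min_recurrence = 5L,
                              n_perm = 99L, seed = 2L)
  g <- res$genes
  # rotation null can never reach 13 concordant lines elsewhere
  expect_equal(g$p[5], 1 / 100)
  expect_true(all(g$flagged[5:10]))
  expect_false(any(g$flagged[-(5:10)]))
  expect_equal(g$count[1], 0)
  expect_equal(nrow(res$regions), 1L)
  expect_equal(res$regions$n_genes, 6L)
  expect_equal(res$regions$direction, "gain")
  expect_error(recurrentAberrations(calls, ann, min_recurrence = 14L),
               "min_recurrence")
})

test_that("the zero-noise pipeline reproduces planted calls and directions", {
  cfg <- tinyConfig(probe_noise_sd = 0)
  ann <- simulateAnnotation(cfg)
  cna <- simulateCna(ann, cfg)
  segs <- segmentAndCall(cna$probes, ann, cfg)
  calls <- geneCalls(segs, ann)
  expected <- matrix(c("loss", "neutral", "gain",
                       "amplification")[match(cna$states, c(-1, 0, 1, 2))],
                     nrow(cna$states), dimnames = dimnames(cna$states))
  expect_identical(calls, expected)
  dirs <- assignGeneDirection(calls)
  truth_dir <- ifelse(rowSums(cna$states > 0) > 0, "gain",
                      ifelse(rowSums(cna$states < 0) > 0, "loss", "none"))
  expect_identical(dirs$direction, unname(truth_dir))
})

test_that("recurrence rotation p-values are super-uniform under a run null", {
  # null tracks: each sample carries one random 4-gene altered run, so
  # run structure exists but positions are exchangeable
  ps <- vapply(1:200, function(rep_) {
    set.seed(rep_)
    n <- 40L
    calls <- vapply(1:6, function(j) {
      v <- rep("neutral", n)
      k <- sample.int(n - 4L, 1L)
      v[k:(k + 3L)] <- sample(c("gain", "loss"), 1L)
      v
    }, character(n))
    dimnames(calls) <- list(sprintf("g%02d", 1:n), sprintf("S%d", 1:6))
    ann <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges((0:(n - 1)) * 100 + 1,
                                                   (0:(n - 1)) * 100 + 90))
    ann$gene_id <- rownames(calls)
    recurrentAberrations(calls, ann, min_recurrence = 2L, n_perm = 60L,
                         seed = 5000L + rep_)$genes$p[17]
  }, 0)
  for (alpha in c(0.05, 0.1, 0.25))
    expect_lte(mean(ps <= alpha),
               alpha + 2 * sqrt(alpha * (1 - alpha) / 200))
})
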
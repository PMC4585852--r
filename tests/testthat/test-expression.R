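test_that("probe filtering applies the QC fractions and median-summarizes", {
  m <- matrix(rnorm(4 * 13), 4, 13,
              dimnames = list(paste0("p", 1:4), paste0("S", 1:13)))
  above <- matrix(TRUE, 4, 13)
  above[1, ] <- c(rep(TRUE, 4), rep(FALSE, 9))   # 4/13 = 30.8% >= 25%
  above[2, ] <- c(rep(TRUE, 2), rep(FALSE, 11))  # 15.4% < 25%
  sat <- matrix(FALSE, 4, 13)
  sat[3, 5] <- TRUE                              # one saturated sample
  kept <- filterProbes(m, list(above_background = above, saturated = sat))
  expect_setequal(rownames(kept), c("p1", "p4"))

  dup <- matrix(c(1, 2, 9, 5, 5, 5), 3, 2,
                dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  out <- filterProbes(dup, probe_gene = c("gX", "gX", "gX"))
  expect_equal(unname(out["gX", ]), c(2, 5))
  expect_error(filterProbes(m, fractions = c(above_background = 1.5,
                                             good_spot = 0.5)),
               "fractions")
})

test_that("quantile normalization equalizes sorted columns", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(paste0("g", 1:3), c("A", "B")))
  out <- normalizeQuantile(m)
  expect_equal(unname(out), matrix(c(2.5, 3.5, 4.5, 2.5, 3.5, 4.5), 3))

  same <- matrix(rep(c(2, 7, 5), 2), 3, 2,
                 dimnames = list(paste0("g", 1:3), c("A", "B")))
  expect_equal(normalizeQuantile(same), same)

  set.seed(1)
  big <- matrix(rnorm(600), 100, 6,
                dimnames = list(paste0("g", 1:100), paste0("S", 1:6)))
  nb <- normalizeQuantile(big)
  sorted <- apply(nb, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1, 1, 1)],
               ignore_attr = TRUE)
  bad <- big
  bad[, 2] <- NA
  expect_error(normalizeQuantile(bad), "all-missing sample")
})

test_that("detectability excludes genes below the first quartile of medians", {
  m <- matrix(rep(1:100, 3), 100, 3,
              dimnames = list(sprintf("g%03d", 1:100), c("A", "B", "C")))
  det <- detectableGenes(m)
  q1 <- quantile(1:100, 0.25, type = 7)  # 25.75
  expect_setequal(det, sprintf("g%03d", which(1:100 >= q1)))

  flat <- matrix(5, 10, 3, dimnames = list(paste0("g", 1:10), c("A", "B", "C")))
  expect_length(detectableGenes(flat), 10L)

  # union across levels: a gene silent in TC but expressed in TL stays
  tc <- m; tl <- m
  tc["g090", ] <- 0
  pe <- PairedExpression(tc, tl)
  expect_true("g090" %in% detectableGenes(pe))
})

test_that("TE is the log2 level difference with antisymmetry and summaries", {
  tc <- matrix(rnorm(30), 10, 3)
  pe <- makePE(tc, tc)
  expect_true(all(teMatrix(pe) == 0))
  pe1 <- makePE(tc, tc + 1)
  expect_equal(teMatrix(pe1), matrix(1, 10, 3), ignore_attr = TRUE)
  # swapping levels flips the sign elementwise
  pe2 <- makePE(tc, tc + rnorm(30))
  swapped <- PairedExpression(translatome(pe2), transcriptome(pe2))
  expect_equal(teMatrix(pe2) + teMatrix(swapped),
               matrix(0, 10, 3), ignore_attr = TRUE)

  set.seed(2)
  base <- matrix(0, 20000, 1, dimnames = list(NULL, "S1"))
  te <- base + rnorm(20000)
  s <- teSummary(te)
  expect_equal(s$iqr, 2 * qnorm(0.75), tolerance = 0.03)
  expect_equal(s$frac_enhanced, pnorm(-1), tolerance = 0.02)
})

test_that("profile clustering separates planted blocks and reports TL cohesion", {
  set.seed(4)
  # two well-separated sample blocks over 60 genes
  block <- rep(c(0, 5), each = 3)
  m <- sapply(block, function(b) rnorm(60, b, 0.2))
  colnames(m) <- paste0("S", 1:6)
  rownames(m) <- paste0("g", 1:60)
  d <- as.dist(1 - cor(m))
  km <- kmeans(t(m), centers = 2, nstart = 10)
  expect_equal(length(unique(km$cluster[1:3])), 1L)
  expect_true(all(km$cluster[1:3] != km$cluster[4:6]))

  # package-level contract: strong shared translational program makes TL
  # profiles each other's nearest neighbours
  cfg <- tinyConfig()
  s <- simulateStudy(cfg)
  cl <- clusterProfiles(s$pe, seed = 1L)
  expect_gte(cl$tl_coclustered, 10)
  expect_s3_class(cl$hclust, "hclust")
  expect_equal(sort(unique(cl$labels)), c("TC", "TL"))

  pe_const <- makePE(cbind(matrix(rnorm(20), 10, 2), rep(1, 10)))
  expect_error(clusterProfiles(pe_const, genes = rownames(pe_const)),
               "constant profile")
})

test_that("anti-correlated profiles sit at the Pearson distance bound", {
  x <- seq(-1, 1, length.out = 10)
  m <- cbind(A = x, B = -x)
  expect_equal(max(as.dist(1 - cor(m))), 2)
})

test_that("delta-CT normalization uses the reference mean per sample", {
  ct <- data.frame(gene = rep(c("T1", "HPRT1", "B2M", "SDHA"), each = 2),
                   sample = "S1",
                   ct = c(20, 20, 18, 18, 20, 20, 22, 22))
  out <- normalizeQpcr(ct, c("HPRT1", "B2M", "SDHA"))
  expect_equal(out["T1", "S1"], 1.0)
  ct2 <- ct
  ct2$ct[ct2$gene == "T1"] <- 19
  expect_equal(normalizeQpcr(ct2, c("HPRT1", "B2M", "SDHA"))["T1", "S1"],
               2.0)
  expect_error(normalizeQpcr(ct, c("HPRT1", "GAPDH")), "GAPDH")
})
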
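test_that("rank product reproduces hand-ranked values and its lower bound", {
  fc <- rbind(gA = c(2.0, 1.5), gB = c(0.5, -0.2), gC = c(-1.0, 0.1))
  colnames(fc) <- c("S1", "S2")
  res <- rankProductTest(fc, "up", n_perm = 50L, seed = 1L)
  expect_equal(res$rp[res$gene_id == "gA"], 1)         # ranked 1 twice
  expect_equal(res$rp[res$gene_id == "gB"], sqrt(6), tolerance = 1e-12)
  expect_equal(res$rp[res$gene_id == "gC"], sqrt(6), tolerance = 1e-12)
  expect_error(rankProductTest(fc, "up", n_perm = 0L), "n_perm")
})

test_that("rank product PFP matches exhaustive enumeration on small designs", {
  fc3 <- rbind(gA = c(2.0, 1.5), gB = c(0.5, -0.2), gC = c(-1.0, 0.1))
  colnames(fc3) <- c("S1", "S2")
  oracle <- rpOracle(fc3, "up")
  res <- rankProductTest(fc3, "up", n_perm = 20000L, seed = 3L)
  expect_equal(res$rp, unname(oracle$rp))
  expect_equal(res$e_fp, unname(oracle$e_fp), tolerance = 0.05)
  expect_equal(res$pfp, unname(oracle$pfp), tolerance = 0.05)

  set.seed(9)
  fc4 <- matrix(rnorm(12), 4, 3,
                dimnames = list(paste0("g", 1:4), paste0("S", 1:3)))
  oracle <- rpOracle(fc4, "down")
  res <- rankProductTest(fc4, "down", n_perm = 20000L, seed = 4L)
  expect_equal(res$rp, unname(oracle$rp))
  expect_equal(res$e_fp, unname(oracle$e_fp), tolerance = 0.1)
  expect_equal(res$pfp, unname(oracle$pfp), tolerance = 0.1)
})

test_that("rank product is invariant to per-sample monotone transforms", {
  set.seed(5)
  fc <- matrix(rnorm(60), 12, 5,
               dimnames = list(paste0("g", 1:12), paste0("S", 1:5)))
  warped <- fc
  warped[, 1] <- exp(fc[, 1])
  warped[, 2] <- fc[, 2]^3
  warped[, 3] <- atan(fc[, 3])
  a <- rankProductTest(fc, "up", n_perm = 50L, seed = 6L)
  b <- rankProductTest(warped, "up", n_perm = 50L, seed = 6L)
  expect_equal(a$rp, b$rp)
  expect_equal(a$e_fp, b$e_fp)
})

test_that("paired t matches the closed form and flags degenerate genes", {
  fc <- rbind(g1 = c(1, 2, 3), g2 = c(0, 0, 0), g3 = c(2, -1, 0.5))
  colnames(fc) <- paste0("S", 1:3)
  res <- pairedTTest(fc)
  expect_equal(res$t[1], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$p[1], 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(res$p[1], 0.07417990, tolerance = 1e-6)
  expect_equal(res$t[2], 0)
  expect_equal(res$p[2], 1)

  con <- rbind(g1 = c(1, 1, 1, 1), g2 = c(1, 2, 0.5, 1.5))
  colnames(con) <- paste0("S", 1:4)
  res <- pairedTTest(con)
  expect_true(res$degenerate[1])
  expect_equal(res$p[1], .Machine$double.xmin)
})

test_that("SAM selects nothing under a flat null and recovers planted shifts", {
  fc0 <- matrix(0, 20, 5,
                dimnames = list(paste0("g", 1:20), paste0("S", 1:5)))
  res0 <- samTest(fc0, n_perm = 20L, seed = 1L)
  expect_true(all(res0$table$d == 0))
  expect_false(any(res0$table$selected))
  expect_error(samTest(fc0, n_perm = 5L), "n_perm")

  set.seed(7)
  n_g <- 300L
  fc <- matrix(rnorm(n_g * 13), n_g, 13,
               dimnames = list(sprintf("g%03d", 1:n_g), sprintf("S%02d", 1:13)))
  planted <- 1:30
  fc[planted, ] <- fc[planted, ] + 3
  res <- samTest(fc, n_perm = 100L, fdr = 0.05, seed = 2L)
  sel <- res$table$gene_id[res$table$selected]
  expect_gte(mean(sprintf("g%03d", planted) %in% sel), 0.8)
  fdr_at_delta <- res$fdr_table$fdr[res$fdr_table$delta == res$delta]
  expect_lte(fdr_at_delta, 0.05)
})

test_that("with equal standard errors SAM reduces to a scaled t statistic", {
  set.seed(8)
  m <- rnorm(50)
  se <- rep(0.4, 50)
  d <- m / (se + 0.1)
  t_like <- m / se
  expect_equal(cor(d, t_like), 1)
})

test_that("the consensus Venn decomposes and reports the shared fraction", {
  mk <- function(universe, rp_up, rp_down, t_sel, sam_sel) {
    rp_u <- data.frame(gene_id = universe,
                       pfp = ifelse(universe %in% rp_up, 0.01, 0.8))
    rp_d <- data.frame(gene_id = universe,
                       pfp = ifelse(universe %in% rp_down, 0.01, 0.8))
    tt <- data.frame(gene_id = universe,
                     q = ifelse(universe %in% t_sel, 0.01, 0.9))
    sam <- list(table = data.frame(gene_id = universe,
                                   selected = universe %in% sam_sel))
    list(rp_up = rp_u, rp_down = rp_d, t = tt, sam = sam)
  }
  u <- letters[1:10]
  # identical sets
  res <- consensusDiffrep(mk(u, c("a", "b"), "c", c("a", "b", "c"),
                             c("a", "b", "c")))
  expect_equal(unname(res$venn["all_three"]), 3)
  expect_equal(res$share_all_three, 1)
  # disjoint sets
  res <- consensusDiffrep(mk(u, "a", NULL, "b", "c"))
  expect_equal(unname(res$venn[c("rp_t", "rp_sam", "t_sam", "all_three")]),
               c(0, 0, 0, 0))
  # A = {a,b,c}, B = {b,c,d}, C = {c,d,e}: A shares 1/3 with B and C
  res <- consensusDiffrep(mk(u, c("a", "b", "c"), NULL, c("b", "c", "d"),
                             c("c", "d", "e")))
  expect_equal(unname(res$venn["all_three"]), 1)
  expect_equal(res$share_all_three, 1 / 3)
  expect_equal(sum(res$venn), length(union(c("a","b","c"),
                                           union(c("b","c","d"),
                                                 c("c","d","e")))))
})

test_that("a gene cannot be rank-product-significant in both directions", {
  cfg <- tinyConfig()
  s <- simulateStudy(cfg)
  dr <- diffRepAll(s$pe, config = cfg)
  up <- dr$rp_up$gene_id[dr$rp_up$pfp <= 0.05]
  down <- dr$rp_down$gene_id[dr$rp_down$pfp <= 0.05]
  expect_length(intersect(up, down), 0L)
})
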
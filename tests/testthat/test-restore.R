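test_that("the four-cell classification maps CNA and TE directions", {
  expect_equal(classifyRestore("gain", "down"), "RESTORE_DOWN")
  expect_equal(classifyRestore("loss", "up"), "RESTORE_UP")
  expect_equal(classifyRestore("loss", "down"), "ENHANCE_DOWN")
  expect_equal(classifyRestore("gain", "up"), "ENHANCE_UP")
  # total and deterministic on the 4-cell domain
  grid <- expand.grid(cna = c("loss", "gain"), te = c("up", "down"),
                      stringsAsFactors = FALSE)
  expect_length(unique(classifyRestore(grid$cna, grid$te)), 4L)
  expect_error(classifyRestore("neutral", "up"))
})

test_that("restore calls intersect diffrep with unambiguous CNA directions", {
  primary <- data.frame(gene_id = c("a", "b", "c", "d"),
                        direction = c("up", "down", "up", "down"))
  gd <- data.frame(gene_id = c("a", "b", "c", "d"),
                   direction = c("loss", "gain", "conflict", "none"),
                   support = c(3L, 5L, 2L, 0L))
  out <- restoreCalls(primary, gd)
  expect_equal(out$gene_id, c("a", "b"))
  expect_equal(out$class, c("RESTORE_UP", "RESTORE_DOWN"))
  expect_equal(out$support, c(3L, 5L))
})

test_that("prevalence binomial is exact and symmetric", {
  expect_equal(prevalenceTest(10, 10)$p, 1.0)
  expect_equal(prevalenceTest(20, 0)$p, 2 * 0.5^20, tolerance = 1e-12)
  expect_equal(prevalenceTest(0, 20)$p, 2 * 0.5^20, tolerance = 1e-12)
  expect_error(prevalenceTest(-1, 5), "non-negative")
  expect_error(prevalenceTest(0, 0), "at least one")
})

test_that("compensatory enrichment reduces to the hypergeometric closed form", {
  universe <- paste0("g", 1:20)
  comp <- paste0("g", 1:10)
  cna <- paste0("g", 1:10)
  res <- compensatoryEnrichment(comp, cna, universe)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)

  # equal proportions: no association
  res <- compensatoryEnrichment(paste0("g", 1:10),
                                paste0("g", c(1:5, 11:15)), universe)
  expect_equal(res$p, 1)
  res <- compensatoryEnrichment(character(0), cna, universe)
  expect_equal(res$p, 1)
  expect_error(compensatoryEnrichment(comp, cna, character(0)),
               "empty universe")
})

test_that("per-line rank-sum matches the exact enumeration case", {
  te <- matrix(c(3, 4, 5, 0, 1, 2), 6, 1,
               dimnames = list(paste0("g", 1:6), "L1"))
  calls <- matrix(c(rep("loss", 3), rep("neutral", 3)), 6, 1,
                  dimnames = dimnames(te))
  expect_warning(res <- perLineWilcoxon(te, calls),
                 "no gained genes in line L1")
  expect_equal(res$p_restore_up, 1 / choose(6, 3))  # 0.05 exactly
  expect_true(is.na(res$p_restore_down))

  # identical value sets cannot look significantly shifted
  te2 <- matrix(c(0, 1, 2, 0, 1, 2), 6, 1, dimnames = dimnames(te))
  res2 <- suppressWarnings(perLineWilcoxon(te2, calls))
  expect_gte(res2$p_restore_up, 0.5)
})

test_that("breadth correlation follows the Pearson closed forms", {
  p_of <- function(x) 10^-x
  expect_equal(breadthCorrelation(p_of(c(1, 2, 3)), c(2, 4, 6))$r, 1)
  expect_equal(breadthCorrelation(p_of(c(1, 2, 3)), c(6, 4, 2))$r, -1)
  expect_equal(breadthCorrelation(p_of(c(1, 2, 3)), c(1, 3, 2))$r, 0.5)
  expect_message(res <- breadthCorrelation(p_of(c(1, 1, 1)), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(res$r))
  expect_error(breadthCorrelation(0.5, 1), "3 lines")
})

test_that("category enrichment computes fold enrichment and BH per category", {
  universe <- paste0("g", 1:100)
  target <- paste0("g", 1:10)
  cats <- list(self = target, other = paste0("g", 51:70))
  res <- categoryEnrichment(cats, target, universe)
  self_row <- res[res$category == "self", ]
  expect_equal(self_row$fold_enrichment, 100 / 10)
  expect_equal(self_row$n_hits, 10)
  expect_lt(self_row$p, 1e-10)
  expect_warning(categoryEnrichment(list(gone = "zzz"), target, universe),
                 "disjoint")
  expect_error(categoryEnrichment(cats, character(0), universe),
               "empty target")
})

test_that("pan-cancer bootstrap hits the add-one floor for a perfect set", {
  genes <- paste0("g", 1:50)
  tab <- data.frame(gene_id = rep(genes, 2),
                    tumor_type = rep(c("T1", "T2"), each = 50),
                    gain_freq = rep(c(1, 0), c(5, 45)),
                    loss_freq = 0)
  res <- panCancerBootstrap(paste0("g", 1:5), tab, "gain_freq",
                            "genomewide", n_boot = 199L, seed = 1L)
  expect_equal(res$p, 1 / 200)
  expect_equal(res$observed, 1)
  expect_error(panCancerBootstrap(paste0("g", 1:5), tab, "gain_freq",
                                  n_boot = 0L), "n_boot")
  expect_error(panCancerBootstrap(genes, tab, "gain_freq",
                                  "cna_background",
                                  cna_genes = paste0("g", 1:10)),
               "background smaller")
})
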
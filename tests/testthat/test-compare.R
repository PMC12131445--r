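mk_records <- function(genes, categories) {
  data.frame(gene = genes,
             category = factor(categories,
                               levels = c("enriched", "group_enriched",
                                          "enhanced", "low_specificity",
                                          "not_detected")),
             stringsAsFactors = FALSE)
}

test_that("classification crosstab counts pairs and conserves margins", {
  a <- mk_records(paste0("g", 1:6),
                  c("enriched", "enriched", "enhanced", "low_specificity",
                    "not_detected", "group_enriched"))
  b <- mk_records(paste0("g", 1:6),
                  c("enriched", "group_enriched", "enhanced", "enhanced",
                    "not_detected", "group_enriched"))
  ct <- classification_crosstab(a, b)
  expect_equal(ct$n, 6L)
  expect_equal(unname(ct$table["enriched", "enriched"]), 1L)
  expect_equal(unname(ct$table["enriched", "group_enriched"]), 1L)
  expect_equal(unname(ct$table["low_specificity", "enhanced"]), 1L)
  expect_equal(sum(ct$table), 6L)
  # identical inputs give a diagonal table
  ct2 <- classification_crosstab(a, a)
  expect_equal(sum(ct2$table) - sum(diag(ct2$table)), 0L)
  expect_equal(unname(rowSums(ct2$table)),
               unname(as.integer(table(a$category))))
  expect_error(classification_crosstab(a, mk_records("zz", "enriched")),
               "intersection")
})

test_that("tau concordance equals brute-force rank correlation", {
  ta <- c(g1 = 0.1, g2 = 0.5, g3 = 0.9, g4 = 0.4, g5 = 0.7)
  tb <- c(g1 = 0.2, g2 = 0.4, g3 = 0.95, g4 = 0.35, g5 = 0.8)
  res <- tau_concordance(ta, tb)
  expect_equal(res$rho, oracle_spearman(ta, tb), tolerance = 1e-12)
  expect_equal(res$n, 5L)
  expect_equal(tau_concordance(ta, ta)$rho, 1)
  # independent scores have near-zero rho
  set.seed(17)
  r <- tau_concordance(stats::setNames(runif(1e4), paste0("g", 1:1e4)),
                       stats::setNames(runif(1e4), paste0("g", 1:1e4)))
  expect_lt(abs(r$rho), 0.05)
  expect_error(tau_concordance(ta[1:2], tb[1:2]), "at least 3")
})

test_that("polyserial estimator recovers the latent correlation", {
  s <- simulate_bivariate_ordinal(0.8, c(-0.5, 0.5, 1.5), 20000, seed = 12L)
  est <- polyserial_correlation(s$x, s$y)
  expect_lt(abs(est$rho - 0.8), 0.03)
  # independence gives near zero
  s0 <- simulate_bivariate_ordinal(0, c(-0.5, 0.5), 20000, seed = 13L)
  expect_lt(abs(polyserial_correlation(s0$x, s0$y)$rho), 0.03)
})

test_that("binary ordinal reduces exactly to the biserial closed form", {
  s <- simulate_bivariate_ordinal(0.5, 0.3, 2000, seed = 14L)
  est <- polyserial_correlation(s$x, s$y)
  hi <- s$y == 2
  p1 <- mean(!hi); p2 <- mean(hi)
  s_x <- sqrt(mean((s$x - mean(s$x))^2))
  biserial <- (mean(s$x[hi]) - mean(s$x[!hi])) * p1 * p2 /
    (stats::dnorm(stats::qnorm(p1)) * s_x)
  expect_equal(est$rho, biserial, tolerance = 1e-10)
})

test_that("polyserial input validation", {
  expect_error(polyserial_correlation(rep(1, 20), rep(1:2, 10)), "constant")
  expect_error(polyserial_correlation(rnorm(20), rep(1, 20)), "2 ordinal")
  expect_error(polyserial_correlation(rnorm(5), rep(1:5)), "at least 10")
  y <- factor(rep(c("a", "c"), 10), levels = c("a", "b", "c"))
  expect_warning(polyserial_correlation(rnorm(20), y), "zero count")
})

test_that("paired tau test matches the exact signed-rank null", {
  set.seed(19)
  ta <- stats::setNames(runif(12, 0.3, 0.9), paste0("g", 1:12))
  tb <- ta - runif(12, 0.01, 0.2)   # distinct nonzero differences
  res <- paired_tau_test(ta, tb)
  expect_equal(res$p_value, oracle_signed_rank_p(ta - tb), tolerance = 1e-10)
  expect_equal(res$n_used, 12L)
  # uniform upward shift: decisive evidence
  big_a <- stats::setNames(runif(200, 0.4, 0.9), paste0("g", 1:200))
  expect_lt(paired_tau_test(big_a, big_a - 0.1)$p_value, 1e-6)
  # identical scores: no evidence
  expect_warning(res0 <- paired_tau_test(big_a, big_a), "zero")
  expect_equal(res0$p_value, 1)
  expect_error(paired_tau_test(ta[1:3], tb[1:3]), "at least 10")
})

test_that("detectability partition enumerates a hand-built toy", {
  genes <- paste0("g", 1:8)
  sc <- mk_records(genes, c("enriched", "enhanced", "not_detected",
                            "not_detected", "low_specificity", "not_detected",
                            "group_enriched", "not_detected"))
  sc$distribution <- factor(c("detected_in_single", "detected_in_many",
                              "not_detected", "not_detected",
                              "detected_in_all", "not_detected",
                              "detected_in_some", "not_detected"))
  bk <- mk_records(genes, c("enriched", "not_detected", "enhanced",
                            "not_detected", "low_specificity", "enriched",
                            "not_detected", "not_detected"))
  bulk_expr <- matrix(c(10, 0, 50, 0, 5, 120, 0, 0,
                        2, 0, 30, 0, 8, 40, 0, 0), ncol = 2,
                      dimnames = list(genes, c("liver", "lung")))
  part <- detectability_partition(sc, bk, bulk_expr)
  expect_setequal(part$both_detected, c("g1", "g5"))
  expect_setequal(part$sc_only, c("g2", "g7"))
  expect_setequal(part$bulk_only, c("g3", "g6"))
  expect_setequal(part$neither, c("g4", "g8"))
  # partition covers the universe exactly once
  expect_equal(sort(c(part$both_detected, part$sc_only, part$bulk_only,
                      part$neither)), sort(genes))
  # bulk-only annotation: max expression and its tissue
  expect_equal(part$bulk_only_expr$max_expr[part$bulk_only_expr$gene == "g3"], 50)
  expect_equal(part$bulk_only_expr$max_tissue[part$bulk_only_expr$gene == "g6"],
               "liver")
  # sc-only annotation carries the distribution category
  expect_equal(as.character(part$sc_only_distribution$distribution[
    part$sc_only_distribution$gene == "g2"]), "detected_in_many")
  # identical detection leaves exclusive sets empty
  p2 <- detectability_partition(sc, sc, bulk_expr)
  expect_equal(length(p2$sc_only), 0L)
  expect_equal(length(p2$bulk_only), 0L)
})
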
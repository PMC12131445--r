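test_that("consensus aggregation is the unweighted cluster mean", {
  m <- matrix(c(10, 1, 30, 3, 8, 2), nrow = 2,
              dimnames = list(c("g1", "g2"), c("cl1", "cl2", "cl3")))
  map <- c(cl1 = "T", cl2 = "T", cl3 = "B")
  cons <- aggregate_to_cell_types(m, map)
  expect_equal(unname(cons$ntpm["g1", "T"]), 20)
  expect_equal(unname(cons$ntpm[, "B"]), unname(m[, "cl3"]))
  expect_equal(cons$clusters$T, c("cl1", "cl2"))
  # one cluster per type: identity (up to column order)
  ident <- aggregate_to_cell_types(m, c(cl1 = "a", cl2 = "b", cl3 = "c"))
  expect_equal(unname(ident$ntpm[, c("a", "b", "c")]), unname(m))
  # permutation of cluster columns commutes
  perm <- aggregate_to_cell_types(m[, c(3, 1, 2)], map)
  expect_equal(perm$ntpm, cons$ntpm)
  expect_error(aggregate_to_cell_types(m, c(cl1 = "T")), "unmapped")
})

test_that("cell-type fractions are tissue-wise proportions", {
  meta <- data.frame(tissue = rep("liver", 100),
                     cell_type = rep(c("hep", "kupffer"), c(70, 30)))
  fr <- cell_type_fractions(meta)
  expect_equal(unname(fr["liver", c("hep", "kupffer")]), c(0.7, 0.3))
  # duplicating every cell changes nothing
  expect_equal(cell_type_fractions(rbind(meta, meta)), fr)
  expect_equal(unname(rowSums(fr)), 1)

  # generator ground truth: equal clusters, no doublets -> uniform fractions
  cfg <- small_cfg(doublet_rate = 0)
  sim <- simulate_counts(simulate_profiles(cfg), cfg)
  meta2 <- merge(sim$metadata, sim$cell_truth[, c("barcode", "cell_type")])
  fr2 <- cell_type_fractions(meta2)
  expect_equal(unname(fr2), matrix(1 / 6, 2, 6), tolerance = 1e-12)
})

test_that("Spearman similarity matches rank-then-Pearson and flags constants", {
  set.seed(3)
  m <- matrix(rlnorm(25), 5, 5,
              dimnames = list(paste0("g", 1:5), paste0("u", 1:5)))
  rho <- spearman_similarity(m)
  expect_equal(unname(diag(rho)), rep(1, 5))
  expect_equal(rho, t(rho))
  expect_equal(rho["u1", "u2"], oracle_spearman(m[, 1], m[, 2]),
               tolerance = 1e-12)
  # reversed ranks give -1
  m2 <- cbind(a = 1:5, b = 5:1)
  rownames(m2) <- paste0("g", 1:5)
  expect_equal(spearman_similarity(m2)["a", "b"], -1)
  # constant unit -> NA entries
  m3 <- cbind(a = c(1, 2, 3), b = c(2, 2, 2))
  rownames(m3) <- paste0("g", 1:3)
  expect_true(is.na(spearman_similarity(m3)["a", "b"]))
  expect_error(spearman_similarity(m[, 1, drop = FALSE]), "at least 2")
})

test_that("Ward dendrogram merges tight pairs before the outlier", {
  units <- c("A", "B", "C", "D", "E")
  rho <- matrix(0.3, 5, 5, dimnames = list(units, units))
  diag(rho) <- 1
  rho["A", "B"] <- rho["B", "A"] <- 0.9
  rho["C", "D"] <- rho["D", "C"] <- 0.9
  rho["E", ] <- rho[, "E"] <- 0.1
  rho["E", "E"] <- 1
  hc <- ward_dendrogram(rho)
  groups <- stats::cutree(hc, k = 3)
  expect_equal(unname(groups["A"]), unname(groups["B"]))
  expect_equal(unname(groups["C"]), unname(groups["D"]))
  expect_equal(sum(groups == groups["E"]), 1L)
  expect_true(all(diff(hc$height) >= -1e-12))

  # two units: single merge at the distance itself
  r2 <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(ward_dendrogram(r2)$height, 0.6)

  # permuting the input yields the same tree metric
  ord <- c(3, 5, 1, 2, 4)
  hc2 <- ward_dendrogram(rho[ord, ord])
  d1 <- as.matrix(stats::cophenetic(hc))[units, units]
  d2 <- as.matrix(stats::cophenetic(hc2))[units, units]
  expect_equal(d1, d2)

  # missing correlations are refused with the offending pair named
  rna <- rho; rna["A", "C"] <- rna["C", "A"] <- NA
  expect_error(ward_dendrogram(rna), "A ~ C")

  # newick export round-trips through ape
  nwk <- as_newick(hc)
  expect_setequal(ape::read.tree(text = nwk)$tip.label, units)
})

test_that("marker z-scores standardise rows and flag constants", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  z <- marker_zscore(m, c("g1", "g2"))
  expect_equal(mean(z["g1", ]), 0)
  expect_equal(stats::sd(z["g1", ]), 1)
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  expect_equal(attr(z, "constant"), "g2")
  # affine invariance
  z2 <- marker_zscore(m * 10 + 3, c("g1"))
  expect_equal(z2["g1", ], z["g1", ])
  expect_error(marker_zscore(m, "nope"), "nope")
})

test_that("percent-of-max follows the display formula and bins", {
  res <- percent_of_max(c(0, 1, 3))
  expect_equal(res$percent, c(0, log2(2) / log2(4) * 100, 100))
  expect_equal(as.character(res$bin), c("<1%", "<75%", ">=75%"))
  expect_equal(percent_of_max(c(5, 1, 0))$percent[1], 100)
  # all-zero input: all cells 0% in the lowest bin
  rz <- percent_of_max(c(0, 0))
  expect_equal(rz$percent, c(0, 0))
  expect_true(all(rz$bin == "<1%"))
  # values always within [0, 100]
  r <- percent_of_max(rpois(100, 10))
  expect_true(all(r$percent >= 0 & r$percent <= 100))
  expect_error(percent_of_max(numeric(0)), "non-empty")
})
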
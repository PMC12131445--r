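sig_fixture <- function() {
  cfg <- small_cfg()
  pr <- simulate_profiles(cfg)
  M <- sweep(pr$means, 2, colSums(pr$means), "/") * 1e6
  rec <- classify_all(M)
  list(cfg = cfg, pr = pr, M = M, rec = rec,
       sig = build_signature(M, rec))
}

test_that("signature holds exactly the enriched genes and flags gaps", {
  fx <- sig_fixture()
  planted <- fx$pr$truth$gene[fx$pr$truth$category == "enriched"]
  called <- fx$rec$gene[fx$rec$category == "enriched"]
  expect_setequal(rownames(fx$sig$S), called)
  expect_true(all(planted %in% rownames(fx$sig$S)))
  expect_equal(length(fx$sig$unidentifiable), 0L)
  # signature rows are a projection of the profile
  expect_equal(fx$sig$S, fx$M[rownames(fx$sig$S), ])

  # removing one type's enriched genes flags that type
  t1 <- colnames(fx$M)[1]
  rec2 <- fx$rec[!(fx$rec$category == "enriched" &
                     fx$rec$elevated_types == t1), ]
  expect_warning(sig2 <- build_signature(fx$M, rec2), t1)
  expect_equal(sig2$unidentifiable, t1)

  expect_error(build_signature(fx$M, fx$rec[fx$rec$category == "enhanced", ]),
               "no enriched")
})

test_that("DWLS recovers exact mixtures to machine precision", {
  fx <- sig_fixture()
  types <- colnames(fx$M)
  p_true <- stats::setNames(c(0.35, 0.25, 0.2, 0.1, 0.07, 0.03), types)
  b <- as.numeric(fx$M %*% p_true)
  names(b) <- rownames(fx$M)
  fit <- dwls_solve(fx$sig, b, fold_seed = 3L)
  expect_lt(max(abs(fit$proportions - p_true)), 1e-6)
  expect_equal(sum(fit$proportions), 1, tolerance = 1e-9)
  expect_true(fit$converged)

  # pure single-type bulk
  e2 <- stats::setNames(c(0, 1, 0, 0, 0, 0), types)
  b2 <- as.numeric(fx$M %*% e2); names(b2) <- rownames(fx$M)
  fit2 <- dwls_solve(fx$sig, b2, fold_seed = 3L)
  expect_lt(abs(fit2$proportions[types[2]] - 1), 1e-6)
})

test_that("the active-set NNLS solver matches an independent implementation", {
  skip_if_not_installed("pracma")
  set.seed(61)
  for (i in 1:25) {
    m <- sample(10:40, 1); n <- sample(2:6, 1)
    A <- matrix(rlnorm(m * n), m, n)
    y <- as.numeric(A %*% runif(n)) + rnorm(m, 0, 0.1)
    got <- sctypemap:::nnls_solve(A, y)
    want <- pracma::lsqnonneg(A, y)$x
    expect_equal(got, want, tolerance = 1e-8)
    # KKT: gradient nonpositive on the active set, zero on the support
    g <- as.numeric(crossprod(A, y - A %*% got))
    expect_true(all(g[got == 0] < 1e-8))
    expect_true(all(abs(g[got > 0]) < 1e-8))
  }
})

test_that("DWLS rejects rank-deficient signatures, naming the collinear type", {
  S <- matrix(rlnorm(40), 20, 2, dimnames = list(paste0("g", 1:20), c("a", "b")))
  S3 <- cbind(S, c = S[, "b"] * 2)
  b <- rowSums(S3)
  expect_error(dwls_solve(S3, b), "rank deficient")
})

test_that("DWLS tolerates noisy mixtures (sanity bound)", {
  fx <- sig_fixture()
  cfgN <- small_cfg(bulk_noise_sd = 0.1)
  set.seed(23)
  P <- sapply(1:5, function(i) { x <- rgamma(6, 1); x / sum(x) })
  rownames(P) <- colnames(fx$M)
  bn <- simulate_bulk(fx$M, P, cfgN)
  l1 <- sapply(1:5, function(i) {
    f <- dwls_solve(fx$sig, stats::setNames(bn[, i], rownames(bn)), fold_seed = 3L)
    sum(abs(f$proportions - P[, i]))
  })
  expect_lt(mean(l1), 0.15)
})

test_that("deconvolve_all ranks the dominant planted type first", {
  fx <- sig_fixture()
  types <- colnames(fx$M)
  # thymus-like mixture dominated by one type
  P <- cbind(thymus = c(0.7, 0.06, 0.06, 0.06, 0.06, 0.06),
             mixed = rep(1 / 6, 6))
  rownames(P) <- types
  bulk <- fx$M %*% P
  res <- deconvolve_all(fx$sig, bulk, k_top = 3, fold_seed = 3L)
  expect_equal(res$top$thymus$cell_type[1], types[1])
  expect_equal(nrow(res$top$thymus), 3L)
  expect_equal(unname(rowSums(res$proportions)), rep(1, 2), tolerance = 1e-9)
  # k_top beyond the number of types lists everything
  res2 <- deconvolve_all(fx$sig, bulk[, 1, drop = FALSE], k_top = 99,
                         fold_seed = 3L)
  expect_equal(nrow(res2$top$thymus), 6L)
})

test_that("hypergeometric overlap matches closed forms and enumeration", {
  universe <- paste0("g", 1:20)
  res <- hypergeometric_overlap(universe[1:5], universe[6:10], universe)
  expect_equal(res$p, 1)   # disjoint: k = 0 always happens
  res2 <- hypergeometric_overlap(universe[1:5], universe[1:5], universe)
  expect_equal(res2$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_error(hypergeometric_overlap("zz", universe[1:2], universe), "subsets")

  # exhaustive enumeration oracle for N <= 12
  for (case in list(c(N = 10, K = 4, n = 3), c(N = 12, K = 6, n = 6),
                    c(N = 9, K = 5, n = 4))) {
    uni <- paste0("u", seq_len(case["N"]))
    A <- uni[seq_len(case["K"])]
    for (k in 0:min(case["K"], case["n"])) {
      B <- c(A[seq_len(k)],
             setdiff(uni, A)[seq_len(case["n"] - k)])
      got <- hypergeometric_overlap(A, B, uni)$p
      want <- oracle_hyper_enum(case["N"], case["K"], case["n"], k)
      expect_equal(got, want, tolerance = 1e-12,
                   label = sprintf("N=%d K=%d n=%d k=%d", case["N"],
                                   case["K"], case["n"], k))
    }
  }
})

test_that("batch overlap applies BH and keeps q >= p", {
  universe <- paste0("g", 1:50)
  sets_a <- list(t1 = universe[1:10], t2 = universe[11:20])
  sets_b <- list(x = universe[1:8], y = universe[30:40])
  res <- hypergeometric_overlap_batch(sets_a, sets_b, universe)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$q >= res$p - 1e-15))
  expect_equal(res$q, stats::p.adjust(res$p, "BH"))
  expect_true(res$significant[res$set_a == "t1" & res$set_b == "x"])
  # p monotone decreasing in overlap for fixed sizes
  ps <- sapply(0:5, function(k) {
    B <- c(universe[seq_len(k)], universe[20 + seq_len(5 - k)])
    hypergeometric_overlap(universe[1:5], B, universe)$p
  })
  expect_true(all(diff(ps) < 0))
})
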
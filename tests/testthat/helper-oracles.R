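# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately re-derive each quantity from its
# definition rather than calling the code under test.

# Specificity classifier by exhaustive search: the group decision scans
# ALL subsets of size 2..max_group_size instead of prefixes.
oracle_classify <- function(x, lim = 1, f = 4, max_group = 10) {
  K <- length(x)
  if (max(x) < lim) return("not_detected")
  ord <- order(-x)
  if (x[ord[1]] > x[ord[2]] && x[ord[1]] >= lim && x[ord[1]] >= f * x[ord[2]]) {
    return("enriched")
  }
  for (g in 2:min(max_group, K - 1)) {
    for (members in utils::combn(K, g, simplify = FALSE)) {
      if (min(x[members]) >= lim &&
          mean(x[members]) >= f * max(x[-members])) {
        return("group_enriched")
      }
    }
  }
  for (i in seq_len(K)) {
    if (x[i] >= lim && x[i] >= f * mean(x[-i])) return("enhanced")
  }
  "low_specificity"
}

# Hypergeometric upper tail by explicit enumeration of all n-subsets of
# the universe (feasible for N <= 12).
oracle_hyper_enum <- function(N, K, n, k) {
  subsets <- utils::combn(N, n, simplify = FALSE)
  hits <- vapply(subsets, function(s) sum(s <= K) >= k, logical(1))
  mean(hits)
}

# Spearman's rho from its definition: average ranks, then Pearson.
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Exact one-sided signed-rank p-value by enumerating all sign vectors
# (requires distinct nonzero |differences|).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  mean(w_all >= w_obs)
}

# TMM factors re-derived from the published formula (doubly trimmed,
# inverse-binomial-variance weighted mean of M-values), including the
# reference-column rule (upper-quartile of count/libsize closest to the
# mean across columns).
oracle_tmm <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, stats::quantile, p = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(j) {
    obs <- counts[, j]; refc <- counts[, ref]
    keep <- obs > 0 & refc > 0
    obs <- obs[keep]; refc <- refc[keep]
    M <- log2((obs / lib[j]) / (refc / lib[ref]))
    A <- (log2(obs / lib[j]) + log2(refc / lib[ref])) / 2
    w <- (lib[j] - obs) / (lib[j] * obs) + (lib[ref] - refc) / (lib[ref] * refc)
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# Small simulation configuration used across unit tests (fast).
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 300L, n_cell_types = 6L, clusters_per_type = 2L,
                   cells_per_cluster = 50L,
                   planted_counts = c(enriched = 30L, group_enriched = 20L,
                                      enhanced = 30L, not_detected = 40L),
                   seed = 101L)
  do.call(sim_config, utils::modifyList(defaults, args))
}
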
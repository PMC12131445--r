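#' Build the enriched-gene signature matrix
#'
#' Restricts the consensus profile to genes classified `enriched` —
#' the signature used to deconvolve bulk tissue expression. Cell types
#' without a single enriched gene cannot be identified by the signature
#' and are flagged.
#'
#' @param profile consensus profile or gene x cell-type nTPM matrix.
#' @param records a `specificity_table` computed on the same profile.
#' @return list of class `signature_matrix`: `S` (signature gene x
#'   cell-type matrix), `genes` (signature gene table) and
#'   `unidentifiable` (flagged cell types).
#' @export
build_signature <- function(profile, records) {
  m <- consensus_matrix(profile)
  sig <- records[records$category == "enriched", , drop = FALSE]
  if (!nrow(sig)) stop("no enriched genes; cannot build a signature", call. = FALSE)
  missing <- setdiff(sig$gene, rownames(m))
  if (length(missing)) {
    stop("signature gene(s) absent from profile: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  S <- m[sig$gene, , drop = FALSE]
  covered <- unique(unlist(strsplit(sig$elevated_types, ";", fixed = TRUE)))
  unident <- setdiff(colnames(m), covered)
  if (length(unident)) {
    warning("cell type(s) without enriched signature genes: ",
            paste(unident, collapse = ", "))
  }
  structure(list(S = S,
                 genes = data.frame(gene = sig$gene, category = sig$category,
                                    elevated_types = sig$elevated_types,
                                    stringsAsFactors = FALSE),
                 unidentifiable = unident),
            class = "signature_matrix")
}

signature_S <- function(x) if (inherits(x, "signature_matrix")) x$S else as.matrix(x)

# Nonnegative least squares by the Lawson-Hanson active-set method.
# The problem is normalised by max|A| first so tolerances are
# scale-free (expression matrices live on a per-million scale).
nnls_solve <- function(A, y) {
  n <- ncol(A)
  s <- max(abs(A))
  if (s <= 0) return(numeric(n))
  A <- A / s; y <- y / s
  tol <- 10 * .Machine$double.eps * max(dim(A)) * sqrt(sum(A^2))
  P <- logical(n)
  x <- numeric(n)
  w <- as.numeric(crossprod(A, y))
  itmax <- 30L * n
  iter <- 0L
  while (any(!P & w > tol) && iter < itmax) {
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      iter <- iter + 1L
      z <- numeric(n)
      co <- qr.coef(qr(A[, P, drop = FALSE]), y)
      co[is.na(co)] <- 0
      z[P] <- co
      if (all(z[P] > 0)) { x <- z; break }
      q <- P & z <= 0
      alpha <- min(x[q] / (x[q] - z[q]))
      x <- x + alpha * (z - x)
      P <- P & x > tol
      x[!P] <- 0
      if (iter >= itmax) break
    }
    w <- as.numeric(crossprod(A, y - A %*% x))
  }
  x
}

wnnls <- function(S, b, w) {
  sw <- sqrt(w)
  nnls_solve(S * sw, b * sw)
}

dampened_weights <- function(pred, d, eps = 1e-8) {
  w <- 1 / pmax(pred, eps)^2
  pmin(w, d * min(w[w > 0]))
}

dwls_iterate <- function(S, b, d, tol, max_iter, eps = 1e-8) {
  x0 <- nnls_solve(S, b)
  p <- if (sum(x0) > 0) x0 / sum(x0) else rep(1 / ncol(S), ncol(S))
  converged <- FALSE
  x <- x0
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- dampened_weights(as.numeric(S %*% p), d, eps)
    x <- wnnls(S, b, w)
    p_new <- if (sum(x) > 0) x / sum(x) else p
    if (max(abs(p_new - p)) < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
  }
  list(p = p, x = x, iterations = iter, converged = converged)
}

#' Dampened weighted least squares deconvolution of one bulk profile
#'
#' Estimates cell-type proportions from a bulk expression vector and an
#' enriched-gene signature matrix. Starting from the nonnegative
#' least-squares solution (normalised to the simplex), the solver
#' iterates weighted nonnegative least squares with weights
#' `1 / max(predicted, eps)^2`, dampened by capping every weight at
#' `d` times the smallest positive weight; the dampening constant `d`
#' is picked from `grid` by k-fold cross-validation over signature
#' genes, minimising held-out weighted squared error (deterministic
#' given `fold_seed`).
#'
#' @param S a `signature_matrix` (or plain gene x cell-type matrix)
#'   with full column rank.
#' @param b bulk expression vector named by gene (aligned to, or a
#'   superset of, the signature genes); renormalised internally to the
#'   per-million scale.
#' @param grid dampening constants to search (default `2^(0:14)`).
#' @param tol convergence tolerance on `max|delta p|`.
#' @param max_iter iteration cap; non-convergence is flagged, not an
#'   error.
#' @param nfolds cross-validation folds for choosing `d`.
#' @param fold_seed seed for the fold assignment.
#' @param eps floor on predicted expression in the weights.
#' @return object of class `dwls_fit`: `proportions` (named, on the
#'   simplex), `dampening`, `iterations`, `converged`,
#'   `residual_norm`, `cv_errors`.
#' @export
dwls_solve <- function(S, b, grid = 2^(0:14), tol = 1e-6, max_iter = 100L,
                       nfolds = 4L, fold_seed = 1L, eps = 1e-8) {
  S <- signature_S(S)
  if (!is.null(names(b))) {
    if (!all(rownames(S) %in% names(b))) {
      stop("`b` lacks signature gene(s): ",
           paste(utils::head(setdiff(rownames(S), names(b)), 5), collapse = ", "),
           call. = FALSE)
    }
    b <- b[rownames(S)]
  } else if (length(b) != nrow(S)) {
    stop("`b` must align with the signature genes", call. = FALSE)
  }
  qrS <- qr(S)
  if (qrS$rank < ncol(S)) {
    bad <- colnames(S)[qrS$pivot[seq(qrS$rank + 1L, ncol(S))]]
    stop("signature matrix is rank deficient; collinear cell type(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (sum(b) <= 0) stop("bulk vector has no signal on signature genes", call. = FALSE)
  b <- as.numeric(b) * 1e6 / sum(b)   # per-million scale, matching the signature

  cv_errors <- rep(NA_real_, length(grid))
  if (length(grid) > 1L) {
    # folds stratified by each signature gene's marker cell type (its
    # argmax column) so every fold retains markers of every type
    strat <- apply(S, 1, which.max)
    folds <- integer(nrow(S))
    with_seed(fold_seed, for (s in unique(strat)) {
      idx <- which(strat == s)
      folds[idx] <- rep_len(seq_len(nfolds), length(idx))[sample(length(idx))]
    })
    for (j in seq_along(grid)) {
      err <- 0
      for (k in seq_len(nfolds)) {
        train <- folds != k
        fit <- dwls_iterate(S[train, , drop = FALSE], b[train], grid[j],
                            tol, max_iter, eps)
        pred <- as.numeric(S[!train, , drop = FALSE] %*% fit$p)
        # rescale predictions to the held-out bulk scale; the held-out
        # error uses uncapped relative weights so it is comparable
        # across dampening constants
        alpha <- sum(pred * b[!train]) / max(sum(pred^2), eps)
        w <- 1 / pmax(pred * alpha, eps)^2
        err <- err + sum(w * (pred * alpha - b[!train])^2)
      }
      cv_errors[j] <- err
    }
    d <- grid[which.min(cv_errors)]
  } else {
    d <- grid[1]
  }

  fit <- dwls_iterate(S, b, d, tol, max_iter, eps)
  if (!fit$converged) {
    warning(sprintf("DWLS did not converge within %d iterations", max_iter))
  }
  structure(list(proportions = stats::setNames(fit$p, colnames(S)),
                 dampening = d,
                 iterations = fit$iterations,
                 converged = fit$converged,
                 residual_norm = sqrt(sum((as.numeric(S %*% fit$x) - b)^2)),
                 cv_errors = stats::setNames(cv_errors, format(grid))),
            class = "dwls_fit")
}

#' @export
print.dwls_fit <- function(x, ...) {
  cat(sprintf("DWLS fit: dampening %g, %d iteration(s)%s\n", x$dampening,
              x$iterations, if (x$converged) "" else " (not converged)"))
  top <- sort(x$proportions, decreasing = TRUE)
  top <- top[seq_len(min(5, length(top)))]
  for (nm in names(top)) cat(sprintf("  %-20s %.4f\n", nm, top[[nm]]))
  invisible(x)
}

#' Deconvolve a panel of bulk tissue profiles
#'
#' Runs [dwls_solve()] on every bulk column and reports, per tissue,
#' the top-k cell types by estimated proportion (ties broken by
#' cell-type id).
#'
#' @param S signature matrix.
#' @param bulk gene x tissue bulk expression matrix.
#' @param k_top number of top cell types to report per tissue.
#' @param ... passed to [dwls_solve()].
#' @return object of class `deconvolution_result`: `proportions`
#'   (tissue x cell-type matrix, rows on the simplex), `top` (list of
#'   per-tissue data frames), `fits`.
#' @export
deconvolve_all <- function(S, bulk, k_top = 5L, ...) {
  Sm <- signature_S(S)
  bulk <- as.matrix(bulk)
  fits <- lapply(stats::setNames(colnames(bulk), colnames(bulk)), function(ti) {
    dwls_solve(S, bulk[, ti], ...)
  })
  props <- do.call(rbind, lapply(fits, function(f) f$proportions))
  rownames(props) <- colnames(bulk)
  top <- lapply(fits, function(f) {
    p <- f$proportions
    ord <- order(-p, names(p))[seq_len(min(k_top, length(p)))]
    data.frame(cell_type = names(p)[ord], proportion = unname(p[ord]),
               stringsAsFactors = FALSE)
  })
  structure(list(proportions = props, top = top, fits = fits),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("Deconvolution of %d bulk profile(s) over %d cell types\n",
              nrow(x$proportions), ncol(x$proportions)))
  for (ti in utils::head(rownames(x$proportions), 5)) {
    t1 <- x$top[[ti]][1, ]
    cat(sprintf("  %-16s top: %s (%.3f)\n", ti, t1$cell_type, t1$proportion))
  }
  invisible(x)
}

#' Hypergeometric overlap test between two gene sets
#'
#' Tests over-representation of the overlap `k = |A intersect B|`
#' against drawing `|B|` genes from a universe of size `N` containing
#' `|A|` successes: `p = P(X >= k)`.
#'
#' @param set_a,set_b gene sets, both subsets of `universe`.
#' @param universe gene universe.
#' @return list with `k`, `K` (= |A|), `n` (= |B|), `N`, `p`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("both sets must be subsets of the universe", call. = FALSE)
  }
  k <- length(intersect(set_a, set_b))
  K <- length(set_a); n <- length(set_b); N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = p)
}

#' Batch hypergeometric overlap tests with BH correction
#'
#' Tests every pair of a named list of cell-type enriched-gene sets
#' against a named list of tissue enriched-gene sets and adjusts the
#' p-values by Benjamini-Hochberg across all pairs.
#'
#' @param sets_a,sets_b named lists of gene sets.
#' @param universe gene universe.
#' @param q_cutoff significance cutoff on the adjusted p-value.
#' @return data.frame with one row per pair: set_a, set_b, k, K, n, N,
#'   p, q, significant.
#' @export
hypergeometric_overlap_batch <- function(sets_a, sets_b, universe,
                                         q_cutoff = 0.05) {
  grid <- expand.grid(a = names(sets_a), b = names(sets_b),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    hypergeometric_overlap(sets_a[[grid$a[i]]], sets_b[[grid$b[i]]], universe)
  })
  out <- data.frame(set_a = grid$a, set_b = grid$b,
                    k = vapply(res, `[[`, 0, "k"),
                    K = vapply(res, `[[`, 0, "K"),
                    n = vapply(res, `[[`, 0, "n"),
                    N = vapply(res, `[[`, 0, "N"),
                    p = vapply(res, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_cutoff
  out
}
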
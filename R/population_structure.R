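## Identity-by-state distances, Ward's minimum-variance clustering, genotype
## PCA, a likelihood-based admixture estimator with the 60% membership rule,
## and Evanno's delta-K model selection over replicate log-likelihoods.

#' Pairwise identity-by-state distance
#'
#' Per marker non-missing in both samples, similarity
#' `(2 - |g_i - g_j|) / 2`; the pair's distance is one minus the mean
#' similarity over shared markers.  Identical genotypes give 0, opposite
#' homozygotes at every locus give 1.
#'
#' @param geno a [genotype_matrix] with >= 2 samples.
#' @return symmetric matrix of class `ibs_dist` with zero diagonal and
#'   sample ids as dimnames.
#' @export
ibs_distance <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  x <- geno$calls
  n <- nrow(x)
  if (n < 2) stop("need >= 2 samples")
  obs <- !is.na(x)
  xz <- x; xz[!obs] <- 0L
  shared <- tcrossprod(obs * 1)                 # markers non-missing in both
  # sum |gi - gj| over shared markers, via indicator expansion of {0,1,2}
  i0 <- (xz == 0L & obs) * 1; i1 <- (xz == 1L & obs) * 1
  i2 <- (xz == 2L & obs) * 1
  absdiff <- tcrossprod(i0, i1) + tcrossprod(i1, i0) +
    tcrossprod(i1, i2) + tcrossprod(i2, i1) +
    2 * (tcrossprod(i0, i2) + tcrossprod(i2, i0))
  if (any(shared[upper.tri(shared)] == 0)) {
    idx <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
    stop("samples ", rownames(x)[idx[1]], " and ", rownames(x)[idx[2]],
         " share no non-missing marker")
  }
  d <- absdiff / (2 * shared)
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  class(d) <- c("ibs_dist", class(d))
  d
}

#' Ward's minimum-variance clustering of a distance matrix
#'
#' Agglomerative merging under Ward's criterion via the Lance-Williams
#' update on squared distances (the `ward.D2` convention of
#' [stats::hclust()]); flat labels are obtained by cutting the merge tree at
#' the height yielding `K` clusters.  Note the agglomeration is greedy: the
#' cut at `K` is not guaranteed to be the global minimizer of within-cluster
#' sums of squares.
#'
#' @param dist a symmetric distance matrix (e.g. from [ibs_distance()]) or a
#'   [stats::dist] object.
#' @param K number of flat clusters, `1 <= K <= n`.
#' @return object of class `ward_cluster`: list with `hclust` (the merge
#'   tree), `labels` (named integer vector), `members` (list of id vectors
#'   per cluster), `K`.
#' @export
ward_cluster <- function(dist, K) {
  if (is.matrix(dist)) dist <- stats::as.dist(dist)
  n <- attr(dist, "Size")
  if (K < 1 || K > n) stop("K must lie in [1, n_samples]")
  hc <- stats::hclust(dist, method = "ward.D2")
  labels <- stats::cutree(hc, k = K)
  structure(list(hclust = hc, labels = labels,
                 members = split(names(labels), labels), K = K),
            class = "ward_cluster")
}

#' PCA of a dosage matrix
#'
#' Missing calls are mean-imputed per marker; columns are then centred and
#' the covariance eigendecomposition is taken (via SVD of the centred
#' matrix).  Eigenvalues are non-increasing and sum to the total variance of
#' the centred, imputed matrix.
#'
#' @param geno a [genotype_matrix] with >= 2 markers.
#' @param n_components leading components to return; truncated (with a
#'   warning) at the matrix rank.
#' @return list with `scores` (samples x components), `eigenvalues` (all
#'   `min(n-1, m)` of them), `var_explained` (proportions).
#' @export
pca_genotypes <- function(geno, n_components = 10) {
  stopifnot(inherits(geno, "genotype_matrix"))
  x <- geno$calls
  if (ncol(x) < 2) stop("need >= 2 markers")
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = min(dim(xc)), nv = 0)
  ev <- sv$d^2 / (nrow(x) - 1)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (n_components > rank) {
    warning("n_components exceeds rank (", rank, "); truncated")
    n_components <- rank
  }
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(scores = scores, eigenvalues = ev,
       var_explained = ev / sum(ev))
}

#' Membership assignment under the 60% rule
#'
#' @param Q samples x K matrix of admixture proportions (rows sum to 1).
#' @param threshold minimum membership for a subgroup call; default 0.60.
#'   A sample is assigned to its argmax subgroup iff its maximum membership
#'   is greater than or equal to the threshold, otherwise to `"mixed"`.
#' @return character vector, `"1"..K` or `"mixed"`, named by sample.
#' @export
assign_membership <- function(Q, threshold = 0.60) {
  mx <- apply(Q, 1, max)
  out <- ifelse(mx >= threshold, as.character(max.col(Q)), "mixed")
  stats::setNames(out, rownames(Q))
}

#' Admixture proportions by alternating EM
#'
#' Maximizes the standard admixture log-likelihood for binomial dosages,
#' `sum_im [ g_im log(pi_im) + (2 - g_im) log(1 - pi_im) ]` with
#' `pi = Q F`, by alternating EM updates of the membership matrix `Q`
#' (rows on the simplex) and the subpopulation allele frequencies `F`.
#' Missing calls simply drop out of the likelihood.  Multiple restarts from
#' Dirichlet-random `Q`; the best-likelihood replicate is returned along
#' with every replicate's final log-likelihood (the input to
#' [evanno_delta_k()]).  The EM likelihood is non-decreasing across
#' iterations; convergence is declared when the gain drops below `tol`.
#'
#' @param geno a (filtered) [genotype_matrix].
#' @param K number of subpopulations, `1 <= K <= n_samples`.
#' @param n_replicates independent restarts; default 10.
#' @param seed integer seed; determines every restart.
#' @param max_iter,tol EM stopping rule (default 2000 iterations / 1e-6
#'   log-likelihood gain).
#' @param threshold membership threshold for [assign_membership()].
#' @return object of class `admixture_result`: list with `Q`, `F`,
#'   `loglik` (best replicate), `replicate_logliks`, `assignments`, `K`.
#' @export
admixture_em <- function(geno, K, n_replicates = 10, seed = 1,
                         max_iter = 2000, tol = 1e-6, threshold = 0.60) {
  stopifnot(inherits(geno, "genotype_matrix"), K >= 1)
  G <- geno$calls
  n <- nrow(G); m <- ncol(G)
  if (K > n) stop("K exceeds the number of samples")
  W <- !is.na(G)
  Gz <- G; Gz[!W] <- 0L
  storage.mode(Gz) <- "double"
  Cz <- (2 - Gz) * W                       # reference-allele counts
  eps <- 1e-9

  run_one <- function(rep_seed) {
    set.seed(rep_seed)
    Q <- rdirichlet(n, rep(1, K))
    F <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)
    ll_old <- -Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      F <- pmin(pmax(F, eps), 1 - eps)
      P <- Q %*% F
      P <- pmin(pmax(P, eps), 1 - eps)
      num_q <- matrix(0, n, K)
      num_f <- den_f <- matrix(0, K, m)
      for (k in seq_len(K)) {
        Ak <- (Gz / P) * outer(Q[, k], F[k, ])          # alt-allele resp.
        Bk <- (Cz / (1 - P)) * outer(Q[, k], 1 - F[k, ])
        num_q[, k] <- rowSums(Ak + Bk)
        num_f[k, ] <- colSums(Ak)
        den_f[k, ] <- colSums(Bk)
      }
      Q <- num_q / (2 * rowSums(W))
      Q <- Q / rowSums(Q)
      tot <- num_f + den_f
      F <- ifelse(tot > 0, num_f / tot, 0.5)
      P <- pmin(pmax(Q %*% F, eps), 1 - eps)
      ll <- sum((Gz * log(P) + Cz * log(1 - P))[W])
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) { ll_old <- ll; break }
      ll_old <- ll
    }
    list(Q = Q, F = F, loglik = ll_old, trace = trace)
  }

  reps <- lapply(seq_len(n_replicates),
                 function(r) run_one(seed + 7919L * r))
  lls <- vapply(reps, `[[`, numeric(1), "loglik")
  best <- reps[[which.max(lls)]]
  rownames(best$Q) <- rownames(G)
  colnames(best$Q) <- paste0("Q", seq_len(K))
  structure(list(Q = best$Q, F = best$F, loglik = best$loglik,
                 loglik_trace = best$trace,
                 replicate_logliks = lls,
                 assignments = assign_membership(best$Q, threshold),
                 K = K),
            class = "admixture_result")
}

#' Evanno delta-K table
#'
#' For replicate log-likelihoods at consecutive K,
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`;
#' defined only at interior K with positive replicate standard deviation
#' (zero-sd rows are flagged `NA`).  `best_K` is the argmax of deltaK.
#'
#' @param logliks named list, names = K values (consecutive integers), each
#'   element a numeric vector of >= 2 replicate log-likelihoods.
#' @return object of class `evanno_table`: data.frame with `K`, `mean_ll`,
#'   `sd_ll`, `delta_k`; attribute `best_K`.
#' @export
evanno_delta_k <- function(logliks) {
  Ks <- as.integer(names(logliks))
  stopifnot(!any(is.na(Ks)), all(diff(Ks) == 1), length(Ks) >= 3)
  if (any(lengths(logliks) < 2))
    stop("need >= 2 replicates at every K")
  mu <- vapply(logliks, mean, numeric(1))
  sdv <- vapply(logliks, stats::sd, numeric(1))
  dk <- rep(NA_real_, length(Ks))
  for (i in seq_along(Ks)[-c(1, length(Ks))]) {
    if (sdv[i] > 0)
      dk[i] <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1]) / sdv[i]
  }
  out <- data.frame(K = Ks, mean_ll = unname(mu), sd_ll = unname(sdv),
                    delta_k = dk)
  if (all(is.na(dk))) {
    best <- NA_integer_
  } else {
    best <- Ks[which.max(dk)]
  }
  structure(out, best_K = best,
            class = c("evanno_table", "data.frame"))
}
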
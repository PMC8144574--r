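#' Extract fitted smooth curves for clustering
#'
#' Pulls the fitted phenotype smooths of the requested (typically significant
#' nonlinear) features from a `de_result` and centers each curve to mean 0
#' over the grid. Optionally scales each curve to unit sd (off by default:
#' the amplitude of an estimated smooth is meaningful).
#'
#' @param de a `de_result` from [run_de()] / [run_continuous_de()].
#' @param ids feature ids to extract; every id must have a converged fit.
#' @param scale also divide each curve by its sd (default FALSE).
#' @return list of class `smooth_curve_set`: `ids`, `grid`, `curves`
#'   (features x grid matrix, rows centered).
#' @export
extract_curves <- function(de, ids, scale = FALSE) {
  stopifnot(inherits(de, "de_result"))
  missing_ids <- setdiff(ids, rownames(de$curves))
  if (length(missing_ids))
    stop("no fit for feature(s): ", paste(missing_ids, collapse = ", "))
  m <- de$curves[ids, , drop = FALSE]
  if (anyNA(m))
    stop("non-converged fit among requested features: ",
         paste(ids[apply(is.na(m), 1, any)], collapse = ", "))
  m <- m - rowMeans(m)
  if (scale) {
    s <- apply(m, 1, stats::sd)
    m <- m / pmax(s, 1e-12)
  }
  structure(list(ids = ids, grid = de$grid, curves = m),
            class = "smooth_curve_set")
}

.curve_matrix <- function(curves) {
  if (inherits(curves, "smooth_curve_set")) curves$curves else as.matrix(curves)
}

# within-cluster dispersion, Tibshirani's form: per cluster, the sum of
# pairwise squared Euclidean distances divided by twice the cluster size
# (equals the within-cluster sum of squares about the centroid)
.wk <- function(X, assignment) {
  sum(vapply(unique(assignment), function(cl) {
    Xc <- X[assignment == cl, , drop = FALSE]
    if (nrow(Xc) < 2) return(0)
    sum(stats::dist(Xc)^2) / nrow(Xc)
  }, numeric(1)))
}

# 1-medoid solution: the point minimizing total squared distance
.medoid1 <- function(X) {
  d2 <- as.matrix(stats::dist(X))^2
  which.min(colSums(d2))
}

#' k-medoid (PAM) clustering of smooth curves
#'
#' Partitioning around medoids (build + swap) under Euclidean distance on the
#' curve vectors. Deterministic for a given input; `seed` is accepted for
#' interface symmetry with [gap_statistic()].
#'
#' @param curves a `smooth_curve_set` or a features x grid matrix.
#' @param k number of clusters (1 <= k <= number of curves).
#' @param seed unused by PAM itself (deterministic); kept for call symmetry.
#' @return list of class `clustering_result`: `k`, `medoid_idx`,
#'   `assignments` (named integer vector), `objective` (sum of distances to
#'   assigned medoids), `within_ss` (sum of squared distances), `mean_curves`
#'   (k x grid matrix of per-cluster means).
#' @export
k_medoids <- function(curves, k, seed = 1L) {
  X <- .curve_matrix(curves)
  if (k > nrow(X)) stop("k must not exceed the number of curves")
  if (k == 1) {
    med <- .medoid1(X)
    asg <- rep(1L, nrow(X))
  } else if (k == nrow(X)) {
    med <- seq_len(k)
    asg <- seq_len(k)
  } else {
    pm <- cluster::pam(X, k, metric = "euclidean")
    med <- pm$id.med
    asg <- pm$clustering
  }
  names(asg) <- rownames(X)
  mean_curves <- t(vapply(seq_len(k), function(cl)
    colMeans(X[asg == cl, , drop = FALSE]), numeric(ncol(X))))
  structure(list(k = k, medoid_idx = med, assignments = asg,
                 objective = sum(sqrt(rowSums((X - X[med[asg], , drop = FALSE])^2))),
                 within_ss = .wk(X, asg),
                 mean_curves = mean_curves),
            class = "clustering_result")
}

#' Gap statistic for the number of curve clusters
#'
#' For k = 1..`k_max`, computes the within-cluster dispersion `W_k` of the
#' PAM solution (per cluster, the pairwise squared distances scaled by twice
#' the cluster size) and compares
#' `log W_k` against reference data drawn uniformly over the
#' principal-component-aligned bounding box of the curves:
#' `Gap(k) = mean_b log W*_kb - log W_k`. The optimal k is the smallest k
#' whose gap is within one standard error of the global maximum of the gap
#' curve (`globalSEmax`; first-maximum variants are fragile when the gap
#' curve is flat near k = 1, as it typically is for sets of fitted smooth
#' curves). All curves identical gives
#' `k_optimal = 1` by definition.
#'
#' @param curves a `smooth_curve_set` or matrix.
#' @param k_max largest k to consider (default 8).
#' @param n_reference number of reference draws (default 50; must be >= 10).
#' @param seed integer seed for the reference draws.
#' @return list of class `gap_result`: `k_optimal`, `gap` (length k_max),
#'   `se` (standard errors), `log_w`, `log_w_ref`.
#' @export
gap_statistic <- function(curves, k_max = 8L, n_reference = 50L, seed = 1L) {
  X <- .curve_matrix(curves)
  if (k_max < 1) stop("k_max must be >= 1")
  if (n_reference < 10) stop("n_reference must be >= 10")
  k_max <- min(k_max, nrow(X) - 1L)
  if (max(stats::dist(X)) < 1e-10) {
    return(structure(list(k_optimal = 1L, gap = NA_real_, se = NA_real_,
                          log_w = NA_real_, log_w_ref = NA_real_),
                     class = "gap_result"))
  }
  wk_all <- function(M) vapply(seq_len(k_max), function(k) {
    if (k == 1) .wk(M, rep(1L, nrow(M)))
    else .wk(M, cluster::pam(M, k, metric = "euclidean")$clustering)
  }, numeric(1))
  log_w <- log(wk_all(X))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  Xp <- Xc %*% sv$v
  rng <- apply(Xp, 2, range)
  set.seed(seed)
  log_ws <- matrix(NA_real_, n_reference, k_max)
  for (b in seq_len(n_reference)) {
    Z <- vapply(seq_len(ncol(Xp)),
                function(j) stats::runif(nrow(X), rng[1, j], rng[2, j]),
                numeric(nrow(X)))
    log_ws[b, ] <- log(wk_all(Z %*% t(sv$v)))
  }
  gap <- colMeans(log_ws) - log_w
  se <- apply(log_ws, 2, stats::sd) * sqrt(1 + 1 / n_reference)
  k_opt <- if (k_max == 1) 1L else
    as.integer(cluster::maxSE(gap, se, method = "globalSEmax"))
  structure(list(k_optimal = k_opt, gap = gap, se = se, log_w = log_w,
                 log_w_ref = colMeans(log_ws)),
            class = "gap_result")
}

#' @export
print.gap_result <- function(x, ...) {
  cat("Gap statistic: optimal k =", x$k_optimal, "\n")
  if (!all(is.na(x$gap)))
    print(round(data.frame(k = seq_along(x$gap), gap = x$gap, se = x$se), 3))
  invisible(x)
}

#' Cluster significant nonlinear smooth curves
#'
#' Convenience wrapper: extract the curves of the given features, choose k by
#' [gap_statistic()], and partition with [k_medoids()].
#'
#' @inheritParams extract_curves
#' @inheritParams gap_statistic
#' @return list with `gap` (a `gap_result`) and `clustering` (a
#'   `clustering_result` at the optimal k).
#' @export
cluster_curves <- function(de, ids, k_max = 8L, n_reference = 50L, seed = 1L,
                           scale = FALSE) {
  cs <- extract_curves(de, ids, scale = scale)
  gap <- gap_statistic(cs, k_max, n_reference, seed)
  list(gap = gap, clustering = k_medoids(cs, gap$k_optimal, seed))
}
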
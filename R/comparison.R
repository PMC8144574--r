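#' Collect per-dimension DE results into one aligned object
#'
#' @param de_list named list of `de_result` objects (or data.frames with
#'   feature_id, p_value, fdr), one per dimension; all must cover the same
#'   features.
#' @return list of class `multi_dim_results`: `feature_id`, `p` and `fdr`
#'   (features x dimensions matrices).
#' @export
multi_dim_results <- function(de_list) {
  tabs <- lapply(de_list, function(d)
    if (inherits(d, "de_result")) d$results else as.data.frame(d))
  ids <- tabs[[1]]$feature_id
  for (t2 in tabs[-1])
    if (!identical(t2$feature_id, ids))
      stop("all dimensions must cover the same features in the same order")
  p <- vapply(tabs, `[[`, numeric(length(ids)), "p_value")
  fdr <- vapply(tabs, `[[`, numeric(length(ids)), "fdr")
  rownames(p) <- rownames(fdr) <- ids
  structure(list(feature_id = ids, p = p, fdr = fdr),
            class = "multi_dim_results")
}

.check_dimension <- function(results, target) {
  if (!target %in% colnames(results$p))
    stop("unknown dimension: ", target, " (have: ",
         paste(colnames(results$p), collapse = ", "), ")")
}

#' Features unique to one symptom dimension
#'
#' A feature is unique to the target dimension when it is significant there
#' (FDR < `fdr_threshold`) while clearly non-significant (p >
#' `other_p_threshold`) in all other subdimensions. The comparison runs over
#' the four subdimensions; `total` (if present) is not used as an "other"
#' dimension, matching the uniqueness definition.
#'
#' @param results a [multi_dim_results()].
#' @param target_dimension the dimension whose unique features are wanted.
#' @param fdr_threshold FDR cut in the target dimension (default 0.05).
#' @param other_p_threshold minimum p required in every other subdimension
#'   (default 0.1).
#' @param others dimensions to compare against; default all subdimensions
#'   except the target (and except `"total"`).
#' @return character vector of unique feature ids.
#' @export
call_unique <- function(results, target_dimension, fdr_threshold = 0.05,
                        other_p_threshold = 0.1, others = NULL) {
  .check_dimension(results, target_dimension)
  if (is.null(others)) {
    others <- setdiff(pcl_dimension_names(FALSE), target_dimension)
    if (!all(others %in% colnames(results$p)))
      others <- setdiff(colnames(results$p), c(target_dimension, "total"))
  }
  for (o in others) .check_dimension(results, o)
  sig <- !is.na(results$fdr[, target_dimension]) &
    results$fdr[, target_dimension] < fdr_threshold
  clear <- rep(TRUE, length(results$feature_id))
  for (o in others)
    clear <- clear & !is.na(results$p[, o]) & results$p[, o] > other_p_threshold
  results$feature_id[sig & clear]
}

#' Pearson correlation of -log10 p across dimensions
#'
#' @param results a [multi_dim_results()].
#' @return symmetric dimensions x dimensions correlation matrix with unit
#'   diagonal; pairs are computed over features with non-NA p in both
#'   dimensions (pairwise deletion). A zero-variance vector yields NA with a
#'   warning.
#' @export
neglogp_correlation <- function(results) {
  nl <- -log10(pmax(results$p, 1e-300))  # cap so p underflow stays finite
  dims <- colnames(nl)
  m <- diag(length(dims))
  dimnames(m) <- list(dims, dims)
  for (i in seq_along(dims)) for (j in seq_len(i - 1L)) {
    ok <- stats::complete.cases(nl[, c(i, j)])
    if (sum(ok) < 3) stop("fewer than 3 shared features for ",
                          dims[i], " vs ", dims[j])
    x <- nl[ok, i]; y <- nl[ok, j]
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
      warning("zero-variance -log10 p vector for ", dims[i], " or ", dims[j])
      m[i, j] <- m[j, i] <- NA_real_
    } else {
      m[i, j] <- m[j, i] <- stats::cor(x, y)
    }
  }
  m
}

#' Region counts of the 4-set Venn diagram of significant features
#'
#' @param results a [multi_dim_results()].
#' @param fdr_threshold significance cut per dimension (default 0.05).
#' @param dimensions the four dimensions to compare; default all
#'   subdimensions except `"total"` (must be exactly 4).
#' @return data.frame with one row per non-empty membership pattern
#'   (all 2^4 - 1 regions): logical columns per dimension and `count`.
#'   Region counts sum to the size of the union of the significant sets.
#' @export
overlap_counts <- function(results, fdr_threshold = 0.05, dimensions = NULL) {
  if (is.null(dimensions))
    dimensions <- setdiff(colnames(results$fdr), "total")
  if (length(dimensions) != 4) stop("exactly 4 dimensions required")
  memb <- vapply(dimensions, function(d)
    !is.na(results$fdr[, d]) & results$fdr[, d] < fdr_threshold,
    logical(length(results$feature_id)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 4))[-1, ]
  names(patterns) <- dimensions
  patterns$count <- apply(patterns, 1, function(pat)
    sum(apply(memb, 1, function(row) all(row == pat))))
  rownames(patterns) <- NULL
  patterns
}

#' Counts of significant features over a grid of p-value thresholds
#'
#' @param results a [multi_dim_results()].
#' @param thresholds numeric thresholds in (0, 1\].
#' @return data.frame: `threshold`, then one count column per dimension
#'   (number of features with p < threshold); monotone non-decreasing in the
#'   threshold.
#' @export
significance_curves <- function(results,
                                thresholds = c(0.001, 0.005, 0.01, 0.05, 0.1)) {
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  out <- data.frame(threshold = thresholds)
  for (d in colnames(results$p))
    out[[d]] <- vapply(thresholds,
                       function(t) sum(results$p[, d] < t, na.rm = TRUE), 0)
  out
}

#' Chi-square goodness-of-fit test of AS event-type proportions
#'
#' Compares the event-type composition of a significant event set against
#' transcriptome-wide background proportions. Expected counts are
#' `total_significant * background proportion`; categories with small
#' expected counts are merged (ascending expected count, ties broken
#' alphabetically) into one combined category until every expected count is
#' at least `min_expected` or only two categories remain, then a Pearson
#' chi-square statistic with `df = #categories - 1` is computed.
#'
#' @param observed named non-negative integer counts per event type for the
#'   significant set.
#' @param background_prop named background proportions (summing to 1) over
#'   the same types.
#' @param min_expected merge threshold on expected counts (default 5).
#' @return list: `statistic`, `df`, `p_value`, `merged` (character vector of
#'   types pooled into the combined category, possibly empty), `observed` and
#'   `expected` after merging.
#' @export
as_proportion_test <- function(observed, background_prop, min_expected = 5) {
  types <- names(background_prop)
  if (is.null(types) || is.null(names(observed)))
    stop("observed and background_prop must be named by event type")
  if (abs(sum(background_prop) - 1) > 1e-6)
    stop("background proportions must sum to 1")
  obs <- stats::setNames(rep(0, length(types)), types)
  obs[names(observed)] <- observed
  total <- sum(obs)
  if (total < 1) stop("observed total must be at least 1")
  exp_ct <- total * background_prop

  # drop types absent from the background (expected 0 and observed 0)
  zero_bg <- background_prop <= 0
  if (any(obs[zero_bg] > 0))
    stop("observed events of a type with zero background proportion")
  obs <- obs[!zero_bg]; exp_ct <- exp_ct[!zero_bg]

  # grow a single combined pool: repeatedly move the smallest-expected
  # remaining single category (ties alphabetical) into the pool while any
  # expected count (single or pool) is below the threshold
  merged <- character(0)
  pool_obs <- 0; pool_exp <- 0
  repeat {
    n_cat <- length(exp_ct) + (length(merged) > 0)
    need <- (length(exp_ct) > 0 && min(exp_ct) < min_expected) ||
      (length(merged) > 0 && pool_exp < min_expected)
    if (!need || n_cat <= 2 || length(exp_ct) == 0) break
    sm <- names(exp_ct)[order(exp_ct, names(exp_ct))][1]
    merged <- sort(c(merged, sm))
    pool_obs <- pool_obs + obs[[sm]]
    pool_exp <- pool_exp + exp_ct[[sm]]
    obs <- obs[names(obs) != sm]
    exp_ct <- exp_ct[names(exp_ct) != sm]
  }
  if (length(merged) > 0) {
    obs <- c(obs, combined = pool_obs)
    exp_ct <- c(exp_ct, combined = pool_exp)
  }
  if (length(exp_ct) < 2) stop("test not defined: fewer than 2 categories")
  stat <- sum((obs - exp_ct)^2 / exp_ct)
  df <- length(exp_ct) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       merged = merged, observed = obs, expected = exp_ct)
}
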
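#' Build a preranked gene list from DE results
#'
#' Genes are scored by `-log10 p` and sorted in decreasing score order; NA
#' p-values are dropped and ties are broken by feature id, so the ranking is
#' deterministic.
#'
#' @param de a `de_result` or a data.frame with `feature_id` and `p_value`.
#' @return numeric vector of scores named by gene id, non-increasing.
#' @export
build_ranking <- function(de) {
  tab <- if (inherits(de, "de_result")) de$results else as.data.frame(de)
  if (nrow(tab) == 0) stop("empty DE result")
  tab <- tab[!is.na(tab$p_value), , drop = FALSE]
  if (nrow(tab) == 0) stop("no usable p-values in the DE result")
  sc <- -log10(pmax(tab$p_value, 1e-300))  # cap so p underflow stays finite
  ord <- order(-sc, tab$feature_id)
  stats::setNames(sc[ord], tab$feature_id[ord])
}

#' Filter gene sets by post-intersection size
#'
#' Set sizes are computed after intersecting each set with the ranked genes;
#' sets outside `[min_size, max_size]` are dropped.
#'
#' @param sets named list of gene-id vectors (see [read_gmt()]).
#' @param ranking a named score vector from [build_ranking()].
#' @param min_size,max_size inclusive size bounds (defaults 15 and 500).
#' @return filtered named list; each element is reduced to its members
#'   present in the ranking.
#' @export
filter_sets <- function(sets, ranking, min_size = 15, max_size = 500) {
  genes <- names(ranking)
  trimmed <- lapply(sets, intersect, genes)
  keep <- lengths(trimmed) >= min_size & lengths(trimmed) <= max_size
  trimmed[keep]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|score|^weight / sum |score|^weight`
#' at set members and `-1 / (N - n_set)` at non-members; the enrichment score
#' is the extremum (largest absolute deviation) of this running sum.
#'
#' @param ranking named non-increasing score vector.
#' @param set character vector of member gene ids (ids absent from the
#'   ranking are ignored).
#' @param weight score-weight exponent (default 1; 0 gives the classic
#'   unweighted KS statistic on ranks).
#' @return list: `es`, `peak` (position of the extremum), `running` (the
#'   full running sum, which ends at 0 up to numerical error). `es` is NA
#'   when the set does not intersect the ranking.
#' @export
enrichment_score <- function(ranking, set, weight = 1) {
  N <- length(ranking)
  hit <- names(ranking) %in% set
  n_set <- sum(hit)
  if (n_set == 0) return(list(es = NA_real_, peak = NA_integer_,
                              running = rep(NA_real_, N)))
  if (n_set == N) stop("gene set covers the whole ranking")
  w <- abs(ranking)^weight
  denom <- sum(w[hit])
  # all-zero member scores: fall back to equal hit weights (classic KS step)
  hit_inc <- if (denom > 0) w / denom else rep(1 / n_set, N)
  inc <- ifelse(hit, hit_inc, -1 / (N - n_set))
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak, running = running)
}

#' Permutation significance and FDR for preranked GSEA
#'
#' Null enrichment scores are generated by gene-label permutation: for each
#' permutation the member labels are reassigned to random positions of the
#' ranking (equivalently, scores are permuted). Nominal p is the one-sided
#' tail frequency with +1 smoothing; NES divides ES by the mean |null ES| of
#' matching sign; FDR q follows the positive/negative pooled-null convention
#' of the classic GSEA method.
#'
#' @param ranking named non-increasing score vector.
#' @param sets filtered named list from [filter_sets()].
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param seed integer seed.
#' @param weight score-weight exponent passed to [enrichment_score()].
#' @return data.frame, one row per set: `set_name`, `size`, `es`, `nes`,
#'   `p_value`, `q_value`, `significant` (q < 0.1) and `fallback_report`
#'   (p < 0.001, flagged when no set reaches q < 0.1).
#' @export
gsea_significance <- function(ranking, sets, n_perm = 1000L, seed = 1L,
                              weight = 1) {
  if (n_perm < 100) warning("n_perm < 100: q-value estimates are unstable")
  if (length(sets) == 0) stop("no gene sets to test")
  N <- length(ranking)
  set.seed(seed)
  sizes <- lengths(lapply(sets, intersect, names(ranking)))
  es_obs <- vapply(sets, function(s) enrichment_score(ranking, s, weight)$es,
                   numeric(1))

  # null ES per set x permutation; hit positions are resampled per set so one
  # shared permutation stream drives all sets reproducibly
  w_all <- abs(ranking)^weight
  null_es <- matrix(NA_real_, length(sets), n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(N)
    for (i in seq_along(sets)) {
      pos <- perm[seq_len(sizes[i])]
      hit <- logical(N); hit[pos] <- TRUE
      dn <- sum(w_all[hit])
      hit_inc <- if (dn > 0) w_all / dn else rep(1 / sizes[i], N)
      inc <- ifelse(hit, hit_inc, -1 / (N - sizes[i]))
      run <- cumsum(inc)
      null_es[i, b] <- run[which.max(abs(run))]
    }
  }

  p <- nes <- numeric(length(sets))
  nes_null <- matrix(NA_real_, length(sets), n_perm)
  for (i in seq_along(sets)) {
    nn <- null_es[i, ]
    same_sign <- if (es_obs[i] >= 0) nn[nn >= 0] else nn[nn < 0]
    p[i] <- (sum(abs(same_sign) >= abs(es_obs[i])) + 1) /
      (length(same_sign) + 1)
    pos_mean <- mean(nn[nn >= 0]); neg_mean <- mean(abs(nn[nn < 0]))
    nes[i] <- if (es_obs[i] >= 0) es_obs[i] / pos_mean else es_obs[i] / neg_mean
    nes_null[i, ] <- ifelse(nn >= 0, nn / pos_mean, nn / neg_mean)
  }

  # pooled-null FDR: for positive NES, fraction of pooled null NES >= nes
  # over fraction of observed NES >= nes (and mirrored for negative)
  q <- vapply(seq_along(sets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      pool <- nes_null[nes_null >= 0]
      num <- mean(pool >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      pool <- nes_null[nes_null < 0]
      num <- mean(pool <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    min(1, num / max(den, 1e-12))
  }, numeric(1))

  any_q <- any(q < 0.1, na.rm = TRUE)
  data.frame(set_name = names(sets), size = as.integer(sizes), es = es_obs,
             nes = nes, p_value = p, q_value = q,
             significant = !is.na(q) & q < 0.1,
             fallback_report = !any_q & p < 0.001,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene sets unique to one symptom dimension
#'
#' A set is unique to the target dimension when it is significant there
#' (q < `q_threshold` or p < `p_fallback`) and clearly non-significant
#' (p > `other_p_threshold`) in all other subdimensions.
#'
#' @param gsea_list named list of [gsea_significance()] tables, one per
#'   dimension; all must cover the same sets.
#' @param target_dimension target dimension name.
#' @param q_threshold FDR cut in the target dimension (default 0.1).
#' @param p_fallback nominal-p fallback cut (default 0.001).
#' @param other_p_threshold minimum p in every other subdimension
#'   (default 0.1).
#' @param others comparison dimensions; default all except target and
#'   `"total"`.
#' @return character vector of unique set names.
#' @export
call_unique_sets <- function(gsea_list, target_dimension, q_threshold = 0.1,
                             p_fallback = 0.001, other_p_threshold = 0.1,
                             others = NULL) {
  if (!target_dimension %in% names(gsea_list))
    stop("unknown dimension: ", target_dimension)
  if (is.null(others))
    others <- setdiff(pcl_dimension_names(FALSE), target_dimension)
  missing_dims <- setdiff(others, names(gsea_list))
  if (length(missing_dims))
    stop("missing dimension(s): ", paste(missing_dims, collapse = ", "))
  tgt <- gsea_list[[target_dimension]]
  hit <- (!is.na(tgt$q_value) & tgt$q_value < q_threshold) |
    (!is.na(tgt$p_value) & tgt$p_value < p_fallback)
  ok <- rep(TRUE, nrow(tgt))
  for (o in others) {
    ot <- gsea_list[[o]]
    po <- ot$p_value[match(tgt$set_name, ot$set_name)]
    ok <- ok & !is.na(po) & po > other_p_threshold
  }
  tgt$set_name[hit & ok]
}

#' Hypergeometric over-representation of a gene list
#'
#' Local annotation of a (dimension-unique) gene list against user-supplied
#' GMT sets: one-sided hypergeometric test per set with BH FDR.
#'
#' @param gene_list character vector of genes of interest.
#' @param sets named list of gene sets.
#' @param universe background gene ids (e.g. all tested genes).
#' @return data.frame: `set_name`, `overlap`, `set_size`, `p_value`, `fdr`,
#'   sorted by p.
#' @export
overrepresentation_test <- function(gene_list, sets, universe) {
  gene_list <- intersect(gene_list, universe)
  sets <- lapply(sets, intersect, universe)
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) stop("no gene sets overlap the universe")
  N <- length(universe); k <- length(gene_list)
  res <- data.frame(
    set_name = names(sets),
    overlap = vapply(sets, function(s) length(intersect(s, gene_list)), 0L),
    set_size = lengths(sets), stringsAsFactors = FALSE, row.names = NULL)
  res$p_value <- stats::phyper(res$overlap - 1, res$set_size,
                               N - res$set_size, k, lower.tail = FALSE)
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$set_name), ]
}
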
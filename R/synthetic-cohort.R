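# Item -> subdimension mapping of the 17-item checklist (DSM-IV four-factor
# split): re-experiencing 5 items, avoidance 2, numbing 5, hyperarousal 5.
.pcl_dimensions <- list(
  reexperiencing = 1:5,
  avoidance      = 6:7,
  numbing        = 8:12,
  hyperarousal   = 13:17
)

# Marginal category probabilities for item scores 1..5, calibrated so the
# total score has mean ~36.6 and SD ~15.4 under the default latent
# correlation structure.
.pcl_item_probs <- c(0.44, 0.23, 0.14, 0.11, 0.08)

# Floor on the within-dimension latent item correlation. Items of the same
# subdimension correlate at max(floor, rho); items of different subdimensions
# correlate at rho (= dimension_correlation).
.within_dim_floor <- 0.55

#' Dimension names used throughout the package
#' @param include_total prepend `"total"` to the four subdimensions.
#' @return character vector.
#' @export
pcl_dimension_names <- function(include_total = TRUE) {
  nm <- names(.pcl_dimensions)
  if (include_total) c("total", nm) else nm
}

#' Generate a synthetic phenotype table
#'
#' Draws 17 ordinal item scores per subject from a latent multivariate normal
#' with an equicorrelated dimension structure, thresholded to the 1-5 scale,
#' then sums items into the total score and the four subdimension scores.
#' Adjustment covariates (age, race indicator, five immune-cell proportions,
#' two surrogate variables) are drawn alongside.
#'
#' @param spec a [cohort_spec()].
#' @param target_band length-2 numeric; expected band for the pairwise
#'   subscale correlations under the spec. A warning is raised when the
#'   empirical correlations of a large cohort (n >= 100) fall outside it.
#' @return data.frame with one row per subject: `subject_id`,
#'   `item_01..item_17`, `total_pcl`, the four subdimension sums, `age`,
#'   `race`, cell proportions (`cd4t`, `cd8t`, `monocytes`, `nk`, `bcells`)
#'   and surrogate variables `sv1`, `sv2`.
#' @export
generate_phenotypes <- function(spec, target_band = c(0.6, 0.85)) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  rho <- spec$dimension_correlation
  w <- max(.within_dim_floor, rho)
  set.seed(spec$seed)

  # latent item scores: shared severity factor (variance rho) + dimension
  # factor (variance w - rho) + item noise (variance 1 - w)
  g <- stats::rnorm(n)
  d <- matrix(stats::rnorm(n * 4), n, 4)
  Z <- matrix(0, n, 17)
  for (k in seq_along(.pcl_dimensions))
    for (j in .pcl_dimensions[[k]])
      Z[, j] <- sqrt(rho) * g + sqrt(w - rho) * d[, k] +
        sqrt(1 - w) * stats::rnorm(n)
  cuts <- stats::qnorm(cumsum(.pcl_item_probs)[1:4])
  items <- matrix(findInterval(Z, cuts) + 1L, n, 17)
  colnames(items) <- sprintf("item_%02d", 1:17)

  sub <- vapply(.pcl_dimensions, function(ix) rowSums(items[, ix, drop = FALSE]),
                numeric(n))
  pheno <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), items,
                      total_pcl = rowSums(items), sub,
                      stringsAsFactors = FALSE)

  pheno$age <- stats::rnorm(n, 52.67, 8.02)
  pheno$race <- stats::rbinom(n, 1L, 0.845)
  # five lymphoid/myeloid proportions; gamma draws scaled to a whole-blood
  # plausible sum (~0.43, the rest being neutrophils etc., not modelled)
  cell_mean <- c(cd4t = 0.15, cd8t = 0.10, monocytes = 0.08, nk = 0.05,
                 bcells = 0.05)
  cells <- vapply(cell_mean, function(m)
    stats::rgamma(n, shape = 20, rate = 20 / m), numeric(n))
  pheno <- cbind(pheno, as.data.frame(cells))
  pheno$sv1 <- stats::rnorm(n)
  pheno$sv2 <- stats::rnorm(n)

  if (n >= 500) {
    cors <- stats::cor(sub)[lower.tri(diag(4))]
    if (any(cors < target_band[1] - 0.05) || any(cors > target_band[2] + 0.05))
      warning(sprintf(
        "subscale correlations [%.2f, %.2f] drift outside the target band [%.2f, %.2f]",
        min(cors), max(cors), target_band[1], target_band[2]))
  }
  pheno
}

# shared helper: phenotype scaled to [0,1] over its observed range
.scale01 <- function(x) {
  r <- range(x)
  if (diff(r) < 1e-12) stop("phenotype has zero range")
  (x - r[1]) / diff(r)
}

# per-feature planted effect on the linear predictor scale
.planted_effect <- function(truth_row, t01) {
  if (truth_row$effect_class == "null") return(rep(0, length(t01)))
  sid <- if (truth_row$effect_class == "linear") "linear" else truth_row$shape_id
  truth_row$amplitude * shape_function(sid, t01)
}

# small covariate contribution shared by the count and TPM generators
.covariate_effect <- function(pheno) {
  0.005 * (pheno$age - mean(pheno$age)) + 0.05 * pheno$race +
    0.3 * (pheno$cd4t - mean(pheno$cd4t)) + 0.02 * pheno$sv1
}

#' Generate a synthetic gene-level count matrix
#'
#' Counts are negative-binomial with
#' `log E[count] = baseline + f_shape(scaled total PCL) * amplitude +
#' covariate effects + log(library factor)`; null genes have amplitude 0.
#' Per-gene dispersions are log-normal around `spec$dispersion_mean`.
#'
#' @param spec a [cohort_spec()].
#' @param phenotypes output of [generate_phenotypes()].
#' @param truth a truth table from [make_truth()] covering all genes.
#' @param library_factors optional per-sample relative library sizes
#'   (positive); default log-normal with sd 0.2 on the log scale.
#' @return integer matrix genes x samples, with the generating library
#'   factors in `attr(, "library_factors")` and per-gene dispersions in
#'   `attr(, "dispersion")`.
#' @export
generate_counts <- function(spec, phenotypes, truth, library_factors = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(phenotypes)
  G <- nrow(truth)
  if (G < spec$n_genes) stop("truth table must cover all genes")
  set.seed(spec$seed + 1L)
  if (is.null(library_factors)) {
    library_factors <- exp(stats::rnorm(n, 0, 0.2))
  } else if (length(library_factors) != n || any(library_factors <= 0)) {
    stop("library_factors must be positive, one per sample")
  }
  t01 <- .scale01(phenotypes$total_pcl)
  covar <- .covariate_effect(phenotypes)
  base <- stats::runif(G, 2, 6)
  disp <- exp(stats::rnorm(G, log(spec$dispersion_mean), 0.5))
  Y <- matrix(0L, G, n, dimnames = list(truth$feature_id, phenotypes$subject_id))
  for (g in seq_len(G)) {
    eta <- base[g] + .planted_effect(truth[g, ], t01) + covar +
      log(library_factors)
    Y[g, ] <- stats::rnbinom(n, mu = exp(eta), size = 1 / disp[g])
  }
  attr(Y, "library_factors") <- library_factors
  attr(Y, "dispersion") <- disp
  Y
}

# normalize columns of a non-negative abundance matrix to `scale` (TPM: 1e6)
.tpm_normalize <- function(A, scale = 1e6) {
  cs <- colSums(A)
  if (any(cs <= 0)) stop("cannot TPM-normalize a column with zero total abundance")
  sweep(A, 2, cs / scale, "/")
}

#' Generate a synthetic isoform TPM matrix
#'
#' Isoform abundances are log-normal with planted phenotype effects on the
#' log scale, then column-normalized so every sample sums to 1e6 (the TPM
#' convention).
#'
#' @inheritParams generate_counts
#' @param truth truth table from [make_truth()] covering all isoforms.
#' @return numeric matrix isoforms x samples; columns sum to 1e6.
#' @export
generate_isoform_tpm <- function(spec, phenotypes, truth) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(phenotypes)
  G <- nrow(truth)
  if (G < spec$n_isoforms) stop("truth table must cover all isoforms")
  set.seed(spec$seed + 2L)
  t01 <- .scale01(phenotypes$total_pcl)
  covar <- .covariate_effect(phenotypes)
  base <- stats::rnorm(G, 3, 1.5)
  A <- matrix(0, G, n, dimnames = list(truth$feature_id, phenotypes$subject_id))
  for (g in seq_len(G)) {
    eta <- base[g] + .planted_effect(truth[g, ], t01) + covar +
      stats::rnorm(n, 0, 0.35)
    A[g, ] <- exp(eta)
  }
  .tpm_normalize(A)
}

# default event-type mix; skipping exons are the modal type, as in
# transcriptome-wide event catalogues
.event_type_mix <- c(SE = 0.435, A3 = 0.16, A5 = 0.12, AF = 0.14,
                     RI = 0.08, MX = 0.035, AL = 0.03)

#' Generate an AS event catalog and the matching transcript TPM matrix
#'
#' Each event gets one inclusion and one exclusion transcript. The per-sample
#' inclusion fraction (PSI) follows a logistic model with the planted effect
#' acting on the logit scale; transcript abundances are the event's total
#' abundance split by PSI, then TPM-normalized per sample.
#'
#' @inheritParams generate_counts
#' @param truth truth table from [make_truth()] covering all events.
#' @param event_type_probs named proportions over the seven event types
#'   {SE, A3, A5, AF, AL, MX, RI}; default makes SE the modal type.
#' @return list with `events` (the catalog data.frame: seqname, gene_id,
#'   event_id, event_type, inclusion_transcripts, total_transcripts),
#'   `tpm` (transcripts x samples matrix, columns summing to 1e6) and
#'   `psi_true` (events x samples matrix of generating inclusion fractions).
#' @export
generate_psi_truth <- function(spec, phenotypes, truth,
                               event_type_probs = .event_type_mix) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(phenotypes)
  E <- nrow(truth)
  if (E < spec$n_events) stop("truth table must cover all events")
  if (abs(sum(event_type_probs) - 1) > 1e-6)
    stop("event_type_probs must sum to 1")
  set.seed(spec$seed + 3L)
  t01 <- .scale01(phenotypes$total_pcl)
  types <- sample(names(event_type_probs), E, replace = TRUE,
                  prob = event_type_probs)
  incl <- sprintf("tx_incl_%04d", seq_len(E))
  excl <- sprintf("tx_excl_%04d", seq_len(E))
  events <- data.frame(
    seqname = sprintf("chr%d", sample(1:22, E, replace = TRUE)),
    gene_id = sprintf("asgene_%04d", seq_len(E)),
    event_id = sprintf("asgene_%04d;%s:ev%04d", seq_len(E), types, seq_len(E)),
    event_type = types,
    inclusion_transcripts = incl,
    total_transcripts = paste(incl, excl, sep = ","),
    stringsAsFactors = FALSE)

  base_logit <- stats::rnorm(E, 0, 1)
  total_ab <- exp(stats::rnorm(E, 4, 1))
  psi <- matrix(0, E, n, dimnames = list(events$event_id, phenotypes$subject_id))
  A <- matrix(0, 2 * E, n,
              dimnames = list(c(incl, excl), phenotypes$subject_id))
  for (e in seq_len(E)) {
    lg <- base_logit[e] + .planted_effect(truth[e, ], t01) +
      stats::rnorm(n, 0, 0.4)
    psi[e, ] <- stats::plogis(lg)
    tot <- total_ab[e] * exp(stats::rnorm(n, 0, 0.3))
    A[e, ] <- tot * psi[e, ]
    A[E + e, ] <- tot * (1 - psi[e, ])
  }
  list(events = events, tpm = .tpm_normalize(A), psi_true = psi)
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_phenotypes()], [make_truth()],
#' [generate_counts()], [generate_isoform_tpm()] and [generate_psi_truth()]
#' under one spec.
#'
#' @param spec a [cohort_spec()].
#' @return list with `phenotypes`, `counts`, `gene_truth`, `isoform_tpm`,
#'   `isoform_truth`, `events`, `event_tpm`, `event_truth`, `psi_true`.
#' @export
simulate_cohort <- function(spec) {
  pheno <- generate_phenotypes(spec)
  gene_truth <- make_truth(spec, spec$n_genes, "gene", 0L)
  iso_truth <- make_truth(spec, spec$n_isoforms, "iso", 101L)
  ev_truth <- make_truth(spec, spec$n_events, "event", 202L)
  counts <- generate_counts(spec, pheno, gene_truth)
  tpm <- generate_isoform_tpm(spec, pheno, iso_truth)
  as <- generate_psi_truth(spec, pheno, ev_truth)
  list(phenotypes = pheno, counts = counts, gene_truth = gene_truth,
       isoform_tpm = tpm, isoform_truth = iso_truth,
       events = as$events, event_tpm = as$tpm, event_truth = ev_truth,
       psi_true = as$psi_true)
}
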
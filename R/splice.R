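#' Percent spliced in (PSI) for one AS event
#'
#' PSI is the ratio of the abundance of the transcripts that include the
#' alternative sequence over the abundance of all transcripts of the event:
#' `psi_ori = sum TPM(inclusion) / sum TPM(total)`. Samples whose total
#' abundance is below `floor` get NA (the ratio is not reliably estimable).
#'
#' @param event one row of an event catalog (see [read_ioe()]).
#' @param tpm transcripts x samples TPM matrix containing every transcript of
#'   the event.
#' @param floor minimum total TPM for a defined PSI (default 1).
#' @return numeric vector of psi_ori in \[0, 1\] (or NA), one per sample.
#' @export
compute_psi <- function(event, tpm, floor = 1) {
  incl <- .split_ids(event$inclusion_transcripts)[[1]]
  tot <- .split_ids(event$total_transcripts)[[1]]
  missing_tx <- setdiff(tot, rownames(tpm))
  if (length(missing_tx))
    stop("event ", event$event_id, ": transcripts not in TPM matrix: ",
         paste(missing_tx, collapse = ", "))
  s_in <- colSums(tpm[incl, , drop = FALSE])
  s_tot <- colSums(tpm[tot, , drop = FALSE])
  psi <- ifelse(s_tot < floor, NA_real_, s_in / s_tot)
  stats::setNames(psi, colnames(tpm))
}

#' PSI matrix for an event catalog
#'
#' @param events event catalog data.frame.
#' @inheritParams compute_psi
#' @return events x samples matrix of psi_ori.
#' @export
compute_psi_matrix <- function(events, tpm, floor = 1) {
  m <- t(vapply(seq_len(nrow(events)),
                function(i) compute_psi(events[i, ], tpm, floor),
                numeric(ncol(tpm))))
  dimnames(m) <- list(events$event_id, colnames(tpm))
  m
}

#' Logit transform of PSI
#'
#' `psi_logit = log(psi_ori / (1 - psi_ori))` (natural log), after clipping
#' psi_ori to `[eps, 1 - eps]` so boundary events stay finite. NA passes
#' through.
#'
#' @param psi_ori numeric vector/matrix in \[0, 1\] (NAs allowed).
#' @param eps clipping bound in (0, 0.5); default 0.01.
#' @return same shape as `psi_ori`, on the log-odds scale.
#' @export
logit_psi <- function(psi_ori, eps = 0.01) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0 || eps >= 0.5)
    stop("eps must lie in (0, 0.5)")
  if (any(!is.na(psi_ori))) {
    rng <- range(psi_ori, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) stop("psi_ori values must lie in [0, 1]")
  }
  x <- pmin(pmax(psi_ori, eps), 1 - eps)
  log(x / (1 - x))
}

#' log(TPM + 1) transform for isoform abundances
#'
#' @param tpm non-negative TPM matrix.
#' @return matrix of the same shape, `log(tpm + 1)` (natural log).
#' @export
transform_isoforms <- function(tpm) {
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  log(tpm + 1)
}

#' Gaussian penalized-spline differential analysis for continuous features
#'
#' The Gaussian analogue of [run_de()] for real-valued feature matrices
#' (isoform log(TPM+1), logit-PSI): per feature, a penalized P-spline smooth
#' of the phenotype plus linear covariates, an F-type test of the smooth,
#' edf, and BH FDR. Samples with NA feature values are dropped per feature;
#' features with too few usable samples (fewer than
#' `n_basis + n_covariates + 2`) or zero variance are excluded from the BH
#' family and reported with NA p-values.
#'
#' @param features features x samples numeric matrix (NAs allowed).
#' @param phenotype numeric phenotype vector aligned with columns.
#' @param covariates optional data.frame of adjustment covariates.
#' @param spec a [smooth_spec()].
#' @param alpha FDR threshold for the significance / nonlinearity call.
#' @param edf_threshold edf above which a significant feature is called
#'   nonlinear.
#' @return object of class `de_result` (same schema as [run_de()]).
#' @export
run_continuous_de <- function(features, phenotype, covariates = NULL,
                              spec = smooth_spec(), alpha = 0.05,
                              edf_threshold = 1.5) {
  features <- as.matrix(features)
  n <- ncol(features)
  if (length(phenotype) != n)
    stop("phenotype must have one value per sample column")
  if (!is.null(covariates)) covariates <- as.data.frame(covariates)
  n_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  min_n <- spec$n_basis + n_cov + 2L
  G <- nrow(features)
  p <- edf <- rep(NA_real_, G)
  curves <- matrix(NA_real_, G, spec$grid_n,
                   dimnames = list(rownames(features), NULL))
  grid <- seq(min(phenotype), max(phenotype), length.out = spec$grid_n)
  n_excluded <- 0L
  for (g in seq_len(G)) {
    y <- features[g, ]
    ok <- !is.na(y)
    if (sum(ok) < min_n || stats::sd(y[ok]) < 1e-12) {
      n_excluded <- n_excluded + 1L
      next
    }
    setup <- .gam_setup(y[ok], phenotype[ok],
                        if (is.null(covariates)) NULL
                        else covariates[ok, , drop = FALSE],
                        rep(0, sum(ok)), spec)
    fit <- tryCatch(
      mgcv::gam(setup$formula, data = setup$df, family = stats::gaussian(),
                method = spec$method, gamma = spec$gamma),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    sm <- summary(fit)
    p[g] <- unname(sm$s.table[1, "p-value"])
    edf[g] <- unname(sm$edf[1])
    # evaluate on the full-cohort grid even if some samples were dropped
    nd <- setup$df[rep(1, spec$grid_n), , drop = FALSE]
    nd$.pheno <- grid
    pr <- mgcv::predict.gam(fit, newdata = nd, type = "terms")
    sm_col <- grep("s(.pheno", colnames(pr), fixed = TRUE)
    cv <- as.numeric(pr[, sm_col])
    curves[g, ] <- cv - mean(cv)
  }
  if (n_excluded > 0)
    message(sprintf("run_continuous_de: %d feature(s) excluded (too few usable samples or zero variance)",
                    n_excluded))
  .assemble_de(rownames(features), p, edf, rowMeans(features, na.rm = TRUE),
               curves, grid, alpha, edf_threshold)
}
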
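#' Specify the penalized smooth used for the phenotype term
#'
#' The phenotype enters the model as a penalized cubic B-spline (P-spline)
#' with a difference penalty whose null space is the linear functions, so an
#' effective degrees of freedom (edf) of 1 corresponds exactly to a linear
#' phenotype effect. Smoothness is selected by REML (or GCV) with a
#' degrees-of-freedom inflation factor that guards against attributing noise
#' wiggliness to the smooth.
#'
#' @param n_basis number of B-spline basis functions (default 10).
#' @param penalty_order order of the difference penalty (default 2; its null
#'   space is then the linear functions).
#' @param method smoothing-parameter selection, `"REML"` or `"GCV"`.
#' @param gamma smoothing-selection df inflation (default 1.3); values > 1
#'   bias the fit toward smoother curves.
#' @param grid_n number of phenotype grid points at which fitted smooths are
#'   evaluated (default 100).
#' @return object of class `smooth_spec`.
#' @export
smooth_spec <- function(n_basis = 10L, penalty_order = 2L,
                        method = c("REML", "GCV"), gamma = 1.3,
                        grid_n = 100L) {
  method <- match.arg(method)
  if (n_basis < 4) stop("n_basis must be at least 4")
  if (penalty_order < 1) stop("penalty_order must be >= 1")
  structure(list(basis = "ps", n_basis = as.integer(n_basis),
                 penalty_order = as.integer(penalty_order),
                 method = if (method == "GCV") "GCV.Cp" else "REML",
                 gamma = gamma, grid_n = as.integer(grid_n)),
            class = "smooth_spec")
}

# assemble the model frame + formula for one feature
.gam_setup <- function(response, phenotype, covariates, offset_log, spec) {
  df <- data.frame(.y = response, .pheno = phenotype)
  cov_terms <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(response))
      stop("covariates must have one row per sample")
    qrX <- qr(cbind(1, as.matrix(covariates)))
    if (qrX$rank < ncol(covariates) + 1) {
      bad <- colnames(covariates)[qrX$pivot[-seq_len(qrX$rank)] - 1]
      stop("singular covariate design; collinear columns: ",
           paste(bad, collapse = ", "))
    }
    df <- cbind(df, covariates)
    cov_terms <- colnames(covariates)
  }
  df$.off <- offset_log
  fml <- stats::as.formula(paste(
    ".y ~ s(.pheno, bs = 'ps', k = ", spec$n_basis,
    ", m = c(2, ", spec$penalty_order, "))",
    if (length(cov_terms)) paste(" +", paste(cov_terms, collapse = " + ")) else "",
    " + offset(.off)"))
  list(df = df, formula = fml)
}

# evaluate the centered fitted smooth on a fixed phenotype grid
.smooth_curve <- function(fit, phenotype, setup_df, grid_n) {
  grid <- seq(min(phenotype), max(phenotype), length.out = grid_n)
  nd <- setup_df[rep(1, grid_n), , drop = FALSE]
  nd$.pheno <- grid
  pr <- mgcv::predict.gam(fit, newdata = nd, type = "terms")
  sm_col <- grep("s(.pheno", colnames(pr), fixed = TRUE)
  curve <- as.numeric(pr[, sm_col])
  list(grid = grid, curve = curve - mean(curve))
}

#' Fit a negative-binomial GAM for one gene
#'
#' Models `log E[count] = offset(log size factor) + intercept + f(phenotype)
#' + linear covariate terms` with a negative-binomial likelihood. The smooth
#' `f` is a penalized P-spline (see [smooth_spec()]); the smoothing parameter
#' and the NB dispersion are estimated jointly by REML. The reported p-value
#' tests `H0: f == 0` (linear part included) with the reference degrees of
#' freedom tied to the edf, following standard penalized-GAM practice.
#'
#' @param gene_counts integer vector of counts, one per sample.
#' @param phenotype numeric phenotype vector (e.g. total PCL score).
#' @param covariates optional data.frame of linear adjustment covariates.
#' @param size_factors positive per-sample factors; enters as
#'   `offset(log(size_factors))`. Default all 1.
#' @param spec a [smooth_spec()].
#' @param sp optional fixed smoothing parameter (overrides REML selection);
#'   a very large value forces the fit into the penalty null space, i.e. a
#'   linear phenotype effect with edf 1.
#' @return list of class `gene_fit`: `coefficients`, `smoothing_parameter`,
#'   `dispersion` (1/theta), `edf`, `p_value`, `fitted_curve` (centered
#'   smooth on `grid`), `grid`, `converged`.
#' @export
fit_nb_gam <- function(gene_counts, phenotype, covariates = NULL,
                       size_factors = NULL, spec = smooth_spec(), sp = NULL) {
  n <- length(gene_counts)
  if (length(phenotype) != n) stop("phenotype length must match sample count")
  if (is.null(size_factors)) size_factors <- rep(1, n)
  if (any(size_factors <= 0)) stop("size factors must be positive")
  if (spec$n_basis >= n) stop("n_basis must be smaller than the sample count")
  setup <- .gam_setup(gene_counts, phenotype, covariates,
                      log(size_factors), spec)
  fit <- tryCatch(
    mgcv::gam(setup$formula, data = setup$df, family = mgcv::nb(),
              method = spec$method, gamma = spec$gamma, sp = sp),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    return(structure(list(coefficients = NULL, smoothing_parameter = NA_real_,
                          dispersion = NA_real_, edf = NA_real_,
                          p_value = NA_real_, fitted_curve = NULL,
                          grid = NULL, converged = FALSE),
                     class = "gene_fit"))
  }
  sm <- summary(fit)
  cv <- .smooth_curve(fit, phenotype, setup$df[1, , drop = FALSE], spec$grid_n)
  structure(list(coefficients = stats::coef(fit),
                 smoothing_parameter = unname(fit$sp[1]),
                 dispersion = 1 / fit$family$getTheta(TRUE),
                 edf = unname(sm$edf[1]),
                 p_value = unname(sm$s.table[1, "p-value"]),
                 fitted_curve = cv$curve, grid = cv$grid,
                 converged = TRUE),
            class = "gene_fit")
}

# shared result assembly: BH over converged features, nonlinearity call
.assemble_de <- function(ids, p, edf, mean_expr, curves, grid,
                         alpha = 0.05, edf_threshold = 1.5) {
  fdr <- rep(NA_real_, length(p))
  conv <- !is.na(p)
  fdr[conv] <- stats::p.adjust(p[conv], method = "BH")
  res <- data.frame(feature_id = ids, p_value = p, fdr = fdr, edf = edf,
                    nonlinear = !is.na(fdr) & fdr < alpha & edf > edf_threshold,
                    mean_expression = mean_expr, stringsAsFactors = FALSE)
  structure(list(results = res, curves = curves, grid = grid,
                 alpha = alpha, edf_threshold = edf_threshold),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  r <- x$results
  cat("DE result:", nrow(r), "features;",
      sum(!is.na(r$fdr) & r$fdr < x$alpha), "significant at FDR <", x$alpha,
      "of which", sum(r$nonlinear), "nonlinear (edf >", x$edf_threshold, ")\n")
  invisible(x)
}

#' Run negative-binomial GAM differential expression
#'
#' Fits [fit_nb_gam()] to every gene of a (filtered) count matrix against one
#' phenotype column, applies Benjamini-Hochberg FDR over the converged fits,
#' and flags nonlinear DE genes as those significant at `alpha` with
#' edf > `edf_threshold`.
#'
#' @param counts genes x samples count matrix (filtered; see
#'   [filter_low_counts()]).
#' @param phenotype numeric phenotype vector aligned with the columns.
#' @param covariates optional data.frame of adjustment covariates.
#' @param spec a [smooth_spec()].
#' @param size_factors optional; estimated by [estimate_size_factors()] when
#'   missing.
#' @param alpha FDR threshold for the significance / nonlinearity call.
#' @param edf_threshold edf above which a significant gene is called
#'   nonlinear (default 1.5).
#' @return object of class `de_result`: `results` (data.frame with
#'   feature_id, p_value, fdr, edf, nonlinear, mean_expression), `curves`
#'   (features x grid matrix of centered fitted smooths) and `grid`.
#'   Non-converged genes carry NA p-values and are excluded from the BH
#'   family.
#' @export
run_de <- function(counts, phenotype, covariates = NULL,
                   spec = smooth_spec(), size_factors = NULL,
                   alpha = 0.05, edf_threshold = 1.5) {
  counts <- as.matrix(counts)
  if (length(phenotype) != ncol(counts))
    stop("phenotype must have one value per sample column")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  G <- nrow(counts)
  p <- edf <- rep(NA_real_, G)
  curves <- matrix(NA_real_, G, spec$grid_n,
                   dimnames = list(rownames(counts), NULL))
  grid <- seq(min(phenotype), max(phenotype), length.out = spec$grid_n)
  for (g in seq_len(G)) {
    f <- fit_nb_gam(counts[g, ], phenotype, covariates, size_factors, spec)
    if (f$converged) {
      p[g] <- f$p_value
      edf[g] <- f$edf
      curves[g, ] <- f$fitted_curve
    }
  }
  .assemble_de(rownames(counts), p, edf, rowMeans(counts), curves, grid,
               alpha, edf_threshold)
}
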
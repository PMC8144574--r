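#' Specify a synthetic cohort
#'
#' A `cohort_spec` collects every parameter of the synthetic cohort generator:
#' cohort size, feature counts, the mixture of null / linear / nonlinear
#' phenotype effects planted in the expression data, effect amplitude,
#' negative-binomial dispersion, and the latent correlation tying the four
#' symptom subdimensions together. The defaults emulate a 226-subject male
#' cohort assessed with the 17-item PCL checklist (items scored 1-5, total
#' score 17-85, four correlated subdimensions).
#'
#' @param n_subjects number of subjects (default 226).
#' @param n_genes number of genes in the count matrix.
#' @param n_isoforms number of isoforms in the TPM matrix.
#' @param n_events number of alternative-splicing events.
#' @param frac_null,frac_linear,frac_nonlinear mixture proportions of planted
#'   phenotype effects; must sum to 1.
#' @param effect_size log-scale amplitude of a planted effect, in units of the
#'   standard deviation of the (standardized) shape function. The default 0.4
#'   gives essentially complete power at the default cohort size.
#' @param dispersion_mean central negative-binomial dispersion (1/theta);
#'   per-gene dispersions are drawn log-normally around it.
#' @param dimension_correlation latent equicorrelation of the four symptom
#'   dimensions, in (0, 1). Controls how similar the subdimension scores are.
#' @param seed integer seed; every generator call derives its randomness from
#'   this (plus the spec), so identical specs give identical cohorts.
#'
#' @return an object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_subjects = 226L,
                        n_genes = 1000L,
                        n_isoforms = 600L,
                        n_events = 200L,
                        frac_null = 0.8,
                        frac_linear = 0.1,
                        frac_nonlinear = 0.1,
                        effect_size = 0.4,
                        dispersion_mean = 0.15,
                        dimension_correlation = 0.5,
                        seed = 1L) {
  counts <- c(n_subjects = n_subjects, n_genes = n_genes,
              n_isoforms = n_isoforms, n_events = n_events)
  if (any(!is.finite(counts)) || any(counts <= 0) || any(counts != round(counts)))
    stop("n_subjects, n_genes, n_isoforms and n_events must be positive integers")
  fr <- c(frac_null, frac_linear, frac_nonlinear)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
    stop("frac_null + frac_linear + frac_nonlinear must equal 1 (all >= 0)")
  if (!is.finite(dimension_correlation) ||
      dimension_correlation <= 0 || dimension_correlation >= 1)
    stop("dimension_correlation must lie in (0, 1)")
  if (dispersion_mean <= 0) stop("dispersion_mean must be positive")
  if (effect_size < 0) stop("effect_size must be non-negative")
  structure(list(
    n_subjects = as.integer(n_subjects), n_genes = as.integer(n_genes),
    n_isoforms = as.integer(n_isoforms), n_events = as.integer(n_events),
    frac_null = frac_null, frac_linear = frac_linear,
    frac_nonlinear = frac_nonlinear, effect_size = effect_size,
    dispersion_mean = dispersion_mean,
    dimension_correlation = dimension_correlation,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_subjects, "subjects,",
      x$n_genes, "genes,", x$n_isoforms, "isoforms,", x$n_events, "AS events\n")
  cat(sprintf("  effect mix null/linear/nonlinear = %.2f/%.2f/%.2f, amplitude %.2f\n",
              x$frac_null, x$frac_linear, x$frac_nonlinear, x$effect_size))
  cat(sprintf("  dispersion_mean %.3f, dimension_correlation %.2f, seed %d\n",
              x$dispersion_mean, x$dimension_correlation, x$seed))
  invisible(x)
}

# Nonlinear dose-response archetypes on the unit interval. Five named shapes;
# each is standardized (mean 0, sd 1 over the evaluation points) before use so
# that `effect_size` means the same thing for every shape.
.shape_functions <- list(
  quadratic  = function(t) (t - 0.3)^2,
  saturating = function(t) 1 - exp(-4 * t),
  sigmoid    = function(t) 1 / (1 + exp(-12 * (t - 0.5))),
  u          = function(t) (2 * t - 1)^2,
  inverted_u = function(t) -(2 * t - 1)^2
)

#' Names of the planted nonlinear shape archetypes
#' @return character vector of the five shape identifiers.
#' @export
shape_names <- function() names(.shape_functions)

#' Evaluate a shape archetype, standardized over the given points
#'
#' @param shape_id one of [shape_names()], or `"linear"`.
#' @param t numeric vector in \[0, 1\].
#' @return numeric vector with mean 0 and sd 1 over `t`.
#' @export
shape_function <- function(shape_id, t) {
  f <- if (shape_id == "linear") function(t) t else .shape_functions[[shape_id]]
  if (is.null(f)) stop("unknown shape_id: ", shape_id)
  g <- f(t)
  s <- stats::sd(g)
  if (s < 1e-12) stop("degenerate shape over supplied points")
  (g - mean(g)) / s
}

#' Build a ground-truth table of planted effects
#'
#' Assigns each feature an effect class (null / linear / nonlinear) according
#' to the spec's mixture proportions; nonlinear features additionally get one
#' of the five shape archetypes (cycled so all shapes are represented) and a
#' signed amplitude.
#'
#' @param spec a [cohort_spec()].
#' @param n number of features (defaults to `spec$n_genes`).
#' @param prefix feature-id prefix, e.g. `"gene"`.
#' @param seed_offset integer mixed into the spec seed so gene / isoform /
#'   event truth tables differ.
#' @return data.frame with columns feature_id, effect_class, shape_id
#'   (NA unless nonlinear), amplitude (0 for null features).
#' @export
make_truth <- function(spec, n = spec$n_genes, prefix = "gene", seed_offset = 0L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + seed_offset)
  n_lin <- round(spec$frac_linear * n)
  n_non <- round(spec$frac_nonlinear * n)
  n_null <- n - n_lin - n_non
  cls <- sample(rep(c("null", "linear", "nonlinear"), c(n_null, n_lin, n_non)))
  shp <- rep(NA_character_, n)
  shp[cls == "nonlinear"] <- rep_len(shape_names(), sum(cls == "nonlinear"))
  amp <- ifelse(cls == "null", 0,
                spec$effect_size * sample(c(-1, 1), n, replace = TRUE))
  data.frame(feature_id = sprintf("%s_%04d", prefix, seq_len(n)),
             effect_class = cls, shape_id = shp, amplitude = amp,
             stringsAsFactors = FALSE)
}
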
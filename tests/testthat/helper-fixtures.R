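# Shared small fixtures, built once per test run.

tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 80L, n_genes = 40L, n_isoforms = 30L, n_events = 20L,
         seed = 11L),
    list(...))
  do.call(cohort_spec, args)
}

# cached small cohort for tests that only need plausible data
.fixture_env <- new.env()
tiny_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- simulate_cohort(tiny_spec())
  .fixture_env$cohort
}

# brute-force Benjamini-Hochberg step-up, independent of stats::p.adjust:
# walk ranks from largest p down, taking the running minimum of (m/rank) * p
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run_min <- 1
  for (r in m:1) {
    run_min <- min(run_min, (m / r) * p[o[r]])
    adj[r] <- run_min
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force GSEA running-sum scan (direct loop, no vectorized shortcuts)
brute_force_es <- function(ranking, set, weight = 1) {
  N <- length(ranking)
  hit <- names(ranking) %in% set
  denom <- sum(abs(ranking[hit])^weight)
  run <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (hit[i]) abs(ranking[i])^weight / denom
      else -1 / (N - sum(hit))
    run[i] <- acc
  }
  run[which.max(abs(run))]
}

# independent textbook chi-square GOF on already-merged categories
textbook_chisq <- function(obs, expected) {
  sum((obs - expected)^2 / expected)
}

# quick NB count vector with an optional planted smooth effect
sim_gene <- function(n, phenotype, f = NULL, base = 4, disp = 0.15,
                     lib = rep(1, n)) {
  eta <- base + log(lib)
  if (!is.null(f)) eta <- eta + f
  stats::rnbinom(n, mu = exp(eta), size = 1 / disp)
}
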
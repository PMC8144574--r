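test_that("cohort_spec validates its parameters", {
  expect_error(cohort_spec(n_genes = -5), "positive integers")
  expect_error(cohort_spec(frac_null = 0.5, frac_linear = 0.1,
                           frac_nonlinear = 0.1), "must equal 1")
  expect_error(cohort_spec(dimension_correlation = 1.2), "in \\(0, 1\\)")
  expect_error(cohort_spec(dimension_correlation = 0), "in \\(0, 1\\)")
  expect_s3_class(cohort_spec(), "cohort_spec")
})

test_that("phenotype tables respect the item structure", {
  spec <- cohort_spec(n_subjects = 226, seed = 4)
  ph <- generate_phenotypes(spec)
  expect_equal(nrow(ph), 226)
  items <- as.matrix(ph[, sprintf("item_%02d", 1:17)])
  expect_true(all(items >= 1 & items <= 5))
  expect_equal(ph$total_pcl, unname(rowSums(items)))
  expect_true(all(ph$total_pcl >= 17 & ph$total_pcl <= 85))
  expect_equal(ph$reexperiencing, unname(rowSums(items[, 1:5])))
  expect_equal(ph$avoidance, unname(rowSums(items[, 6:7])))
  expect_equal(ph$numbing, unname(rowSums(items[, 8:12])))
  expect_equal(ph$hyperarousal, unname(rowSums(items[, 13:17])))
  cells <- as.matrix(ph[, c("cd4t", "cd8t", "monocytes", "nk", "bcells")])
  expect_true(all(cells >= 0))
  expect_true(all(rowSums(cells) <= 1))
})

test_that("generation is deterministic given the seed", {
  spec <- tiny_spec(seed = 99)
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
  spec2 <- tiny_spec(seed = 100)
  expect_false(identical(generate_phenotypes(spec), generate_phenotypes(spec2)))
})

test_that("near-unit dimension correlation drives subscale correlations above 0.9", {
  spec <- cohort_spec(n_subjects = 500, dimension_correlation = 0.99, seed = 7)
  ph <- suppressWarnings(generate_phenotypes(spec))
  sub <- as.matrix(ph[, pcl_dimension_names(FALSE)])
  cors <- cor(sub)[lower.tri(diag(4))]
  expect_true(all(cors > 0.9))
})

test_that("default marginals match the cohort the generator emulates", {
  # mean total within +-3 of 36.59 averaged over seeds; subscale correlations
  # inside the documented band
  means <- vapply(1:20, function(s) {
    mean(generate_phenotypes(cohort_spec(n_subjects = 226, seed = s))$total_pcl)
  }, numeric(1))
  expect_lt(abs(mean(means) - 36.59), 3)
  ph <- generate_phenotypes(cohort_spec(n_subjects = 2000, seed = 1))
  expect_lt(abs(sd(ph$total_pcl) - 15.45), 2.5)
  cors <- cor(as.matrix(ph[, pcl_dimension_names(FALSE)]))[lower.tri(diag(4))]
  expect_true(all(cors > 0.55 & cors < 0.9))
})

test_that("null genes are uncorrelated with the phenotype", {
  spec <- cohort_spec(n_subjects = 500, n_genes = 120, frac_null = 1,
                      frac_linear = 0, frac_nonlinear = 0, seed = 2)
  ph <- generate_phenotypes(spec)
  truth <- make_truth(spec)
  expect_true(all(truth$amplitude == 0))
  counts <- generate_counts(spec, ph, truth)
  r <- apply(counts, 1, function(y) cor(y, ph$total_pcl, method = "spearman"))
  expect_lt(mean(abs(r)), 0.08)
  expect_lt(max(abs(r)), 0.25)
})

test_that("library factors scale expected column sums", {
  spec <- tiny_spec(frac_null = 1, frac_linear = 0, frac_nonlinear = 0,
                    n_genes = 300L)
  ph <- generate_phenotypes(spec)
  truth <- make_truth(spec, spec$n_genes)
  lf <- rep(1, spec$n_subjects); lf[1] <- 2
  counts <- generate_counts(spec, ph, truth, library_factors = lf)
  base <- mean(colSums(counts)[-1])
  expect_lt(abs(colSums(counts)[1] / base - 2), 0.35)
  expect_error(generate_counts(spec, ph, truth, library_factors = rep(-1, 80)),
               "positive")
})

test_that("truth tables carry shapes only for nonlinear features", {
  truth <- make_truth(tiny_spec(), n = 200, prefix = "g")
  expect_true(all(is.na(truth$shape_id[truth$effect_class != "nonlinear"])))
  expect_true(all(truth$shape_id[truth$effect_class == "nonlinear"] %in%
                    shape_names()))
  expect_true(all(truth$amplitude[truth$effect_class == "null"] == 0))
  expect_setequal(unique(truth$shape_id[truth$effect_class == "nonlinear"]),
                  shape_names())
})

test_that("TPM matrices are column-normalized to one million", {
  co <- tiny_cohort()
  expect_true(all(abs(colSums(co$isoform_tpm) - 1e6) < 1e-6 * 1e6))
  expect_true(all(abs(colSums(co$event_tpm) - 1e6) < 1e-6 * 1e6))
})

test_that("event catalogs satisfy the inclusion-subset invariant", {
  co <- tiny_cohort()
  ev <- co$events
  for (i in seq_len(nrow(ev))) {
    incl <- strsplit(ev$inclusion_transcripts[i], ",")[[1]]
    tot <- strsplit(ev$total_transcripts[i], ",")[[1]]
    expect_true(all(incl %in% tot))
    expect_gt(length(setdiff(tot, incl)), 0)
  }
  expect_true(all(ev$event_type %in% c("SE","A3","A5","AF","AL","MX","RI")))
  # SE is the modal type under the default mix
  big <- generate_psi_truth(cohort_spec(n_subjects = 30, n_events = 600,
                                        seed = 3),
                            generate_phenotypes(cohort_spec(n_subjects = 30,
                                                            seed = 3)),
                            make_truth(cohort_spec(n_subjects = 30,
                                                   n_events = 600, seed = 3),
                                       600, "ev"))
  expect_equal(names(which.max(table(big$events$event_type))), "SE")
})

test_that("planted-zero PSI slopes leave PSI uncorrelated with the phenotype", {
  spec <- cohort_spec(n_subjects = 400, n_events = 80, frac_null = 1,
                      frac_linear = 0, frac_nonlinear = 0, seed = 5)
  ph <- generate_phenotypes(spec)
  truth <- make_truth(spec, spec$n_events, "ev")
  as <- generate_psi_truth(spec, ph, truth)
  r <- apply(as$psi_true, 1, function(p) cor(p, ph$total_pcl))
  expect_lt(mean(abs(r)), 0.08)
})
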
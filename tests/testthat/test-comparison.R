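# builds a multi_dim_results from explicit p/fdr matrices
mdr_fixture <- function(p, fdr = NULL) {
  dims <- colnames(p)
  if (is.null(fdr)) fdr <- apply(p, 2, function(x) p.adjust(x, "BH"))
  de_list <- lapply(seq_along(dims), function(j)
    data.frame(feature_id = rownames(p), p_value = p[, j], fdr = fdr[, j],
               stringsAsFactors = FALSE))
  names(de_list) <- dims
  multi_dim_results(de_list)
}

dims4 <- c("reexperiencing", "avoidance", "numbing", "hyperarousal")

test_that("uniqueness calling follows the FDR-and-clear-p definition", {
  p <- matrix(0.5, 3, 4, dimnames = list(c("g1", "g2", "g3"), dims4))
  fdr <- p
  # g1: significant in target, clear everywhere else -> unique
  fdr["g1", "numbing"] <- 0.04
  p["g1", c("reexperiencing", "avoidance", "hyperarousal")] <- c(0.2, 0.3, 0.5)
  # g2: significant in target but one other dimension at p = 0.05 -> not unique
  fdr["g2", "numbing"] <- 0.04
  p["g2", c("reexperiencing", "avoidance", "hyperarousal")] <- c(0.05, 0.3, 0.5)
  res <- mdr_fixture(p, fdr)
  expect_equal(call_unique(res, "numbing"), "g1")
  expect_error(call_unique(res, "nosuch"), "unknown dimension")
  # empty significant set -> empty output
  res0 <- mdr_fixture(matrix(0.9, 2, 4,
                             dimnames = list(c("a", "b"), dims4)))
  expect_length(call_unique(res0, "avoidance"), 0)
  # by construction no unique feature is significant elsewhere at p <= 0.1
  expect_true(all(res$p["g1", setdiff(dims4, "numbing")] > 0.1))
})

test_that("hand-enumerated uniqueness on a mixed fixture is reproduced", {
  set.seed(70)
  ids <- sprintf("g%02d", 1:30)
  p <- matrix(runif(120, 0.11, 1), 30, 4, dimnames = list(ids, dims4))
  fdr <- matrix(1, 30, 4, dimnames = list(ids, dims4))
  planted <- list(reexperiencing = c("g01", "g05"), avoidance = "g10",
                  numbing = character(0), hyperarousal = c("g20", "g21", "g22"))
  for (d in dims4) fdr[planted[[d]], d] <- 0.01
  # spoil g05: low p in another dimension
  p["g05", "numbing"] <- 0.02
  res <- mdr_fixture(p, fdr)
  expect_equal(call_unique(res, "reexperiencing"), "g01")
  expect_equal(call_unique(res, "avoidance"), "g10")
  expect_length(call_unique(res, "numbing"), 0)
  expect_equal(call_unique(res, "hyperarousal"), c("g20", "g21", "g22"))
})

test_that("-log p correlations are exact in degenerate cases and base-free", {
  set.seed(71)
  ids <- paste0("g", 1:200)
  p1 <- runif(200, 1e-6, 1)
  p <- cbind(total = p1, reexperiencing = p1, avoidance = runif(200),
             numbing = runif(200), hyperarousal = runif(200))
  rownames(p) <- ids
  res <- mdr_fixture(p)
  m <- neglogp_correlation(res)
  expect_equal(unname(diag(m)), rep(1, 5))
  expect_equal(m["total", "reexperiencing"], 1)        # identical p vectors
  expect_equal(m, t(m))
  # base choice only rescales the vectors; Pearson r is unchanged
  nl10 <- -log10(p[, "avoidance"]); nln <- -log(p[, "avoidance"])
  expect_equal(cor(nl10, -log10(p[, "numbing"])),
               cor(nln, -log(p[, "numbing"])))
})

test_that("independent uniform p vectors correlate near zero", {
  set.seed(72)
  p <- matrix(runif(4e4), 1e4, 4, dimnames = list(paste0("g", 1:1e4), dims4))
  m <- neglogp_correlation(mdr_fixture(p))
  off <- m[lower.tri(m)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("Venn region counts match brute-force enumeration", {
  set.seed(73)
  ids <- paste0("g", 1:50)
  fdr <- matrix(runif(200), 50, 4, dimnames = list(ids, dims4))
  p <- fdr
  res <- mdr_fixture(p, fdr)
  oc <- overlap_counts(res, fdr_threshold = 0.3)
  memb <- fdr < 0.3
  # brute force: count features per membership pattern
  for (i in seq_len(nrow(oc))) {
    pat <- unlist(oc[i, dims4])
    expect_equal(oc$count[i],
                 sum(apply(memb, 1, function(r) all(r == pat))))
  }
  expect_equal(sum(oc$count), sum(rowSums(memb) > 0))
  # disjoint sets: no intersection region occupied
  fdr2 <- matrix(1, 4, 4, dimnames = list(paste0("h", 1:4), dims4))
  diag(fdr2) <- 0.01
  oc2 <- overlap_counts(mdr_fixture(fdr2, fdr2), 0.05)
  multi <- rowSums(oc2[, dims4]) > 1
  expect_true(all(oc2$count[multi] == 0))
  # identical sets: only the 4-way region occupied
  fdr3 <- matrix(0.01, 3, 4, dimnames = list(paste0("k", 1:3), dims4))
  oc3 <- overlap_counts(mdr_fixture(fdr3, fdr3), 0.05)
  expect_equal(oc3$count[rowSums(oc3[, dims4]) == 4], 3)
  expect_true(all(oc3$count[rowSums(oc3[, dims4]) < 4] == 0))
})

test_that("threshold curves count significant features monotonically", {
  set.seed(74)
  p <- matrix(runif(4000), 1000, 4, dimnames = list(paste0("g", 1:1000), dims4))
  res <- mdr_fixture(p)
  sc <- significance_curves(res, thresholds = c(0.001, 0.05, 0.5, 1))
  for (d in dims4) {
    expect_true(all(diff(sc[[d]]) >= 0))
    expect_equal(sc[[d]][4], 1000)            # t = 1 counts everything
  }
  expect_lt(abs(sc[["reexperiencing"]][2] - 50), 25)  # binomial expectation
  expect_error(significance_curves(res, thresholds = c(0, 0.5)), "\\(0, 1\\]")
})

test_that("the proportion test matches hand evaluation and chisq.test", {
  # worked two-category case: observed (10, 40) vs equal background
  out <- as_proportion_test(c(SE = 10, AF = 40), c(SE = 0.5, AF = 0.5))
  expect_equal(out$statistic, 18)
  expect_equal(out$df, 1L)
  expect_equal(out$p_value, pchisq(18, 1, lower.tail = FALSE))
  # observed exactly proportional to background -> statistic 0, p 1
  bg <- c(SE = 0.5, A3 = 0.3, AF = 0.2)
  out0 <- as_proportion_test(c(SE = 50, A3 = 30, AF = 20), bg)
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p_value, 1)
})

test_that("proportion-test merging pools small expected categories deterministically", {
  bg <- c(SE = 0.5, A3 = 0.2, A5 = 0.15, AF = 0.09, AL = 0.03, MX = 0.02,
          RI = 0.01)
  obs <- c(SE = 30, A3 = 10, A5 = 8, AF = 6, AL = 3, MX = 2, RI = 1)
  out <- as_proportion_test(obs, bg)
  # expected for AL/MX/RI/AF are 1.8/1.2/0.6/5.4 on n=60: the sub-5 ones merge
  expect_true(all(c("AL", "MX", "RI") %in% out$merged))
  expect_true(all(out$expected >= 5 | names(out$expected) == "combined" |
                    length(out$expected) == 2))
  # merging preserves totals
  expect_equal(sum(out$expected), 60)
  expect_equal(sum(out$observed), 60)
  # statistic equals an independent textbook implementation on the merged table
  expect_equal(out$statistic, textbook_chisq(out$observed, out$expected),
               tolerance = 1e-10)
  # and equals chisq.test on the merged categories
  ref <- suppressWarnings(
    chisq.test(out$observed, p = out$expected / sum(out$expected)))
  expect_equal(out$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(out$df, unname(ref$parameter))
})

test_that("random proportion-test inputs agree with the oracle", {
  set.seed(75)
  types <- c("SE", "A3", "A5", "AF", "AL", "MX", "RI")
  for (i in 1:20) {
    bg <- rgamma(7, 2); bg <- setNames(bg / sum(bg), types)
    obs <- setNames(rmultinom(1, sample(20:200, 1), bg)[, 1], types)
    out <- as_proportion_test(obs, bg)
    expect_equal(out$statistic, textbook_chisq(out$observed, out$expected),
                 tolerance = 1e-10)
    expect_equal(sum(out$expected), sum(obs), tolerance = 1e-9)
  }
})
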
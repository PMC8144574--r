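ranking_fixture <- function(n = 20, seed = 80) {
  set.seed(seed)
  p <- sort(runif(n, 1e-5, 1))
  setNames(-log10(p), sprintf("g%02d", seq_len(n)))
}

test_that("rankings are ordered, deduplicated and tie-stable", {
  de <- data.frame(feature_id = c("b", "a", "c", "d"),
                   p_value = c(0.01, 0.001, 0.1, NA))
  rk <- build_ranking(de)
  expect_equal(names(rk), c("a", "b", "c"))
  expect_equal(unname(rk), c(3, 2, 1))
  # equal p: deterministic order by id
  de2 <- data.frame(feature_id = c("z", "m"), p_value = c(0.05, 0.05))
  expect_equal(names(build_ranking(de2)), c("m", "z"))
  # p = 1 ranks last with score 0
  de3 <- data.frame(feature_id = c("x", "y"), p_value = c(1, 0.5))
  rk3 <- build_ranking(de3)
  expect_equal(names(rk3)[2], "x")
  expect_equal(unname(rk3[2]), 0)
  expect_error(build_ranking(de[0, ]), "empty")
})

test_that("gene sets are filtered by post-intersection size", {
  rk <- ranking_fixture(100, seed = 81)
  sets <- list(small = names(rk)[1:10],
               partial = c(names(rk)[1:14], paste0("zz", 1:6)),
               keep = names(rk)[1:20],
               big = c(names(rk), paste0("x", 1:600)))
  out <- filter_sets(sets, rk, min_size = 15, max_size = 90)
  expect_equal(names(out), "keep")
  out2 <- filter_sets(sets, rk, min_size = 15, max_size = 500)
  expect_false("partial" %in% names(out2))  # 14 in-ranking members < 15
})

test_that("enrichment scores equal the brute-force running-sum scan", {
  rk <- ranking_fixture(20)
  set.seed(82)
  for (i in 1:10) {
    set <- sample(names(rk), sample(3:8, 1))
    es <- enrichment_score(rk, set)
    expect_equal(es$es, brute_force_es(rk, set), tolerance = 1e-12)
    expect_lt(abs(es$running[20]), 1e-9)  # conservation of increments
    expect_lte(abs(es$es), 1)
  }
  # top of the list -> positive ES; bottom -> negative
  expect_gt(enrichment_score(rk, names(rk)[1:5])$es, 0)
  expect_lt(enrichment_score(rk, names(rk)[16:20])$es, 0)
})

test_that("weight 0 reduces the ES to the classic KS statistic on ranks", {
  rk <- ranking_fixture(30, seed = 83)
  set <- names(rk)[c(2, 5, 9, 20, 25)]
  es0 <- enrichment_score(rk, set, weight = 0)
  # classic KS: steps of 1/n_set at members, -1/(N - n_set) elsewhere
  N <- 30; hit <- names(rk) %in% set
  run <- cumsum(ifelse(hit, 1 / 5, -1 / (N - 5)))
  expect_equal(es0$es, run[which.max(abs(run))], tolerance = 1e-12)
})

test_that("enrichment scores match the fgsea reference statistic", {
  skip_if_not_installed("fgsea")
  rk <- sort(rnorm(50, 0, 2), decreasing = TRUE)
  names(rk) <- paste0("g", 1:50)
  set.seed(84)
  for (i in 1:5) {
    set <- sample(names(rk), 8)
    ours <- enrichment_score(rk, set, weight = 1)$es
    ref <- fgsea::calcGseaStat(rk, selectedStats = which(names(rk) %in% set),
                               gseaParam = 1, scoreType = "std")
    expect_equal(ours, unname(ref), tolerance = 1e-10)
  }
})

test_that("permutation significance is calibrated, smoothed and deterministic", {
  set.seed(85)
  rk <- setNames(abs(rnorm(200, 0, 1.5)), paste0("g", 1:200))
  rk <- sort(rk, decreasing = TRUE)
  sets <- lapply(1:30, function(i) sample(names(rk), 20))
  names(sets) <- paste0("s", 1:30)
  res <- gsea_significance(rk, sets, n_perm = 200, seed = 5)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(res$q_value >= 0 & res$q_value <= 1, na.rm = TRUE))
  # random sets on a random ranking: roughly nominal rate at p < 0.05
  expect_lt(mean(res$p_value < 0.05), 0.25)
  res2 <- gsea_significance(rk, sets, n_perm = 200, seed = 5)
  expect_identical(res$q_value, res2$q_value)
  expect_warning(gsea_significance(rk, sets[1:2], n_perm = 50, seed = 1),
                 "unstable")
})

test_that("a set planted at the top of a structured ranking reaches q < 0.1", {
  set.seed(86)
  scores <- sort(c(runif(30, 3, 6), runif(270, 0, 1)), decreasing = TRUE)
  rk <- setNames(scores, paste0("g", 1:300))
  sets <- c(list(planted = names(rk)[1:25]),
            lapply(1:10, function(i) sample(names(rk)[31:300], 25)))
  names(sets)[-1] <- paste0("bg", 1:10)
  res <- gsea_significance(rk, sets, n_perm = 500, seed = 6)
  expect_lt(res$q_value[res$set_name == "planted"], 0.1)
  expect_gt(res$es[res$set_name == "planted"], 0)
})

test_that("unique gene-set calling honors both significance branches", {
  mk <- function(q, p) data.frame(set_name = c("s1", "s2"),
                                  q_value = q, p_value = p)
  gl <- list(
    reexperiencing = mk(c(0.05, 0.30), c(0.01, 0.0005)),
    avoidance = mk(c(0.9, 0.9), c(0.2, 0.2)),
    numbing = mk(c(0.9, 0.9), c(0.2, 0.2)),
    hyperarousal = mk(c(0.9, 0.9), c(0.2, 0.2)))
  # s1 via the q-branch, s2 via the p-fallback branch
  expect_setequal(call_unique_sets(gl, "reexperiencing"), c("s1", "s2"))
  gl$avoidance$p_value <- c(0.09, 0.2)  # s1 no longer clear elsewhere
  expect_equal(call_unique_sets(gl, "reexperiencing"), "s2")
  expect_error(call_unique_sets(gl[1:3], "reexperiencing"), "missing dimension")
})

test_that("GMT round-trip and hypergeometric over-representation", {
  sets <- list(alpha = paste0("g", 1:20), beta = paste0("g", 15:40))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
  universe <- paste0("g", 1:100)
  hits <- paste0("g", 1:10)  # all inside alpha
  res <- overrepresentation_test(hits, sets, universe)
  expect_equal(res$p_value[res$set_name == "alpha"],
               phyper(9, 20, 80, 10, lower.tail = FALSE))
  expect_equal(res$fdr, p.adjust(res$p_value, "BH"))
  expect_lt(res$p_value[1], res$p_value[2])
})
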
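test_that("Jaccard distances follow set arithmetic", {
  prof <- rbind(a = c(GH5 = 1, GH13 = 1, PL1 = 0),
                b = c(1, 1, 0),
                c = c(0, 1, 1),
                d = c(0, 0, 1))
  colnames(prof) <- c("GH5", "GH13", "PL1")
  d <- jaccard_matrix(prof)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2 / 3)   # one shared of three in the union
  expect_equal(d["a", "d"], 1)       # disjoint sets
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  # two empty genomes: defined as 0 with a warning
  prof2 <- rbind(x = c(1, 0), y = c(0, 0), z = c(0, 0))
  colnames(prof2) <- c("GH5", "GH13")
  expect_warning(d2 <- jaccard_matrix(prof2), "empty")
  expect_equal(d2["y", "z"], 0)
})

test_that("PCoA reproduces Euclidean-embeddable distances", {
  # all-zero distances: coordinates collapse to the origin
  d0 <- matrix(0, 4, 4)
  expect_true(all(abs(pcoa(d0)$coordinates) < 1e-12))
  # equilateral triangle: recomputed pairwise distances equal 1
  d1 <- 1 - diag(3)
  ord <- pcoa(d1)
  back <- as.matrix(dist(ord$coordinates))
  expect_true(all(abs(back[upper.tri(back)] - 1) < 1e-8))
  # random Euclidean configurations round-trip within 1e-8
  set.seed(9)
  for (i in 1:10) {
    pts <- matrix(rnorm(12 * 5), 12, 5)
    dd <- as.matrix(dist(pts))
    o <- pcoa(dd)
    expect_true(all(o$eigenvalues > -1e-10))
    back <- as.matrix(dist(o$coordinates))
    expect_lt(max(abs(back - dd)), 1e-8)
    expect_true(all(diff(o$eigenvalues) <= 1e-10))
  }
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

two_clouds <- function(n_per = 20, sep = 10) {
  pts <- rbind(matrix(rnorm(n_per * 2, 0, 0.1), ncol = 2),
               matrix(rnorm(n_per * 2, sep, 0.1), ncol = 2))
  list(d = as.matrix(dist(pts)),
       groups = rep(c("u", "v"), each = n_per))
}

test_that("ANOSIM and PERMANOVA behave at the separation extremes", {
  set.seed(11)
  tc <- two_clouds()
  an <- anosim(tc$d, tc$groups, n_permutations = 199, seed = 4)
  expect_equal(an$statistic, 1)             # all between > all within
  expect_equal(an$p, 1 / 200)
  pm <- permanova(tc$d, tc$groups, n_permutations = 199, seed = 4)
  expect_equal(pm$p, 1 / 200)
  expect_gt(pm$statistic, 100)
  # all distances equal: R = 0 by tied ranks
  deq <- matrix(1, 6, 6); diag(deq) <- 0
  expect_equal(anosim(deq, rep(c("u", "v"), 3), n_permutations = 19,
                      seed = 1)$statistic, 0)
  # reproducibility under a fixed seed, invariance to reordering
  an2 <- anosim(tc$d, tc$groups, n_permutations = 199, seed = 4)
  expect_identical(an, an2)
  perm <- sample(nrow(tc$d))
  an3 <- anosim(tc$d[perm, perm], tc$groups[perm], n_permutations = 199,
                seed = 4)
  expect_equal(an3$statistic, an$statistic)
  expect_error(anosim(tc$d, c(rep("u", nrow(tc$d) - 1), "v"), 99, 1),
               "size 1")
})

test_that("ANOSIM R matches the rank formula on a four-point toy", {
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1   # within group 1
  d[3, 4] <- d[4, 3] <- 0.2   # within group 2
  d[1, 3] <- d[3, 1] <- 0.8
  d[1, 4] <- d[4, 1] <- 0.9
  d[2, 3] <- d[3, 2] <- 0.7
  d[2, 4] <- d[4, 2] <- 0.6
  groups <- c("u", "u", "v", "v")
  # ranks: within = {1, 2}, between = {3, 4, 5, 6}; M = 6
  r_expected <- (mean(c(3, 4, 5, 6)) - mean(c(1, 2))) / (6 / 2)
  got <- anosim(d, groups, n_permutations = 99, seed = 1)
  expect_equal(got$statistic, r_expected)
})

test_that("Kruskal-Wallis enrichment flags strong signals and adjusts p", {
  prof <- matrix(0, 40, 3,
                 dimnames = list(NULL, c("GH5", "GH13", "CONST")))
  groups <- rep(c("u", "v"), each = 20)
  prof[groups == "u", "GH5"] <- 1          # 100% vs 0%
  set.seed(2)
  prof[, "GH13"] <- rbinom(40, 1, 0.5)     # no group signal
  res <- kw_enrichment(prof, groups)
  expect_true(res$significant[res$family_label == "GH5"])
  expect_equal(res$enriched_group[res$family_label == "GH5"], "u")
  expect_false(res$tested[res$family_label == "CONST"])
  expect_true(all(res$p_adjusted >= res$p, na.rm = TRUE))
})

test_that("BH adjustment equals the literal step-up on known and random input", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(13)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_identical(stats::p.adjust(p, "BH"), bh_oracle(p))
  }
})

test_that("LDA effect size separates constructed extremes", {
  set.seed(21)
  n <- 30
  groups <- rep(c("u", "v"), each = n / 2)
  prof <- matrix(abs(rnorm(n * 4, 50, 5)), n, 4,
                 dimnames = list(NULL, paste0("GH", 1:4)))
  prof[groups == "u", "GH1"] <- 1e5 + rnorm(n / 2, 0, 1)
  prof[groups == "v", "GH1"] <- 1 + abs(rnorm(n / 2, 0, 0.1))
  res <- lda_effect_size(prof, groups, seed = 5)
  expect_gte(res$lda_score[res$family_label == "GH1"], 4)
  expect_true(res$lda_flagged[res$family_label == "GH1"])
  # identical distributions never reach the screen
  prof2 <- matrix(rep(prof[, 2], 4), n, 4,
                  dimnames = list(NULL, paste0("GH", 1:4)))
  res2 <- lda_effect_size(prof2, groups, seed = 5)
  expect_true(all(is.na(res2$lda_score)))
  expect_error(lda_effect_size(prof, rep(c("u", "v", "w"), each = 10)),
               "2 groups")
})

test_that("profile matrix aggregates modules at both granularities", {
  calls <- list(
    A = call_consensus(rbind(make_hits("a1", hmmer = c("GH5_2", "GH5_46")),
                             make_hits("a2", hmmer = "CBM6"))),
    B = call_consensus(make_hits("b1", hmmer = c("GH5_2", "PL1"))))
  fam <- profile_matrix(calls, values = "count", granularity = "family")
  expect_equal(fam["A", "GH5"], 2)
  expect_equal(fam["B", "GH5"], 1)
  sub <- profile_matrix(calls, granularity = "subfamily")
  expect_true(all(c("GH5_2", "GH5_46") %in% colnames(sub)))
  pres <- profile_matrix(calls)
  expect_true(all(pres %in% c(0, 1)))
})
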
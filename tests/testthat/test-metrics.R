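test_that("family diversity collapses subfamilies at family granularity", {
  calls <- call_consensus(rbind(
    make_hits("g1", hmmer = c("GH5_2", "CBM6")),
    make_hits("g2", hmmer = "GH5_46"),
    make_hits("g3", hmmer = "GH13_10")))
  expect_equal(family_diversity(calls, "GH", "family"), 2L)
  expect_equal(family_diversity(calls, "GH", "subfamily"), 3L)
  expect_equal(family_diversity(calls, "PL", "family"), 0L)
  expect_equal(family_diversity(calls, "CBM", "family"), 1L)
  # any module of the class implies diversity >= 1
  expect_gte(family_diversity(calls, "GH", "family"), 1L)
})

make_meta <- function(ids, completeness, contamination) {
  data.frame(genome_id = ids, class = "c", order = "o", family = "f",
             habitat = "marine", completeness = completeness,
             contamination = contamination, genome_size_bp = 4e6,
             n_proteins = 3000L, stringsAsFactors = FALSE)
}

fake_calls <- function(n_classified) {
  if (n_classified == 0) {
    return(call_consensus(make_hits("x")))
  }
  call_consensus(do.call(rbind, lapply(seq_len(n_classified), function(i) {
    make_hits(paste0("g", i), hmmer = "GH5")
  })))
}

test_that("quality filter applies strict boundaries and is idempotent", {
  meta <- make_meta(paste0("G", 1:4), c(74.9, 75.0, 75.1, 90),
                    c(5, 5, 5, 10.0))
  calls <- list(G1 = fake_calls(12), G2 = fake_calls(12),
                G3 = fake_calls(12), G4 = fake_calls(12))
  qf <- quality_filter(meta, calls)
  expect_equal(qf$retained, "G3")
  expect_match(qf$log$reason[qf$log$genome_id == "G1"], "completeness")
  expect_match(qf$log$reason[qf$log$genome_id == "G4"], "contamination")
  # CAZyme count boundary: 9 excluded, 10 retained
  meta2 <- make_meta(c("A", "B"), 90, 1)
  calls2 <- list(A = fake_calls(9), B = fake_calls(10))
  expect_equal(quality_filter(meta2, calls2)$retained, "B")
  # idempotence
  kept <- quality_filter(meta, calls)$retained
  again <- quality_filter(meta[meta$genome_id %in% kept, ], calls[kept])
  expect_equal(again$retained, kept)
  # calls without metadata is a hard error
  expect_error(quality_filter(meta2, list(A = fake_calls(9),
                                          Z = fake_calls(20))), "Z")
})

test_that("small classes pool into 'other class' with counts conserved", {
  meta <- make_meta(paste0("G", 1:25), 90, 1)
  meta$class <- c(rep("big", 15), rep("small", 9), "tiny")
  out <- group_small_classes(meta, min_n = 10)
  expect_equal(sum(out$class == "other class"), 10L)
  expect_equal(sum(out$class == "big"), 15L)
  expect_equal(nrow(out), nrow(meta))
  # a class with exactly min_n genomes is unchanged
  meta2 <- make_meta(paste0("G", 1:10), 90, 1)
  meta2$class <- "edge"
  expect_equal(unique(group_small_classes(meta2, 10)$class), "edge")
})

test_that("rare families use a strict occupancy threshold", {
  prof <- matrix(0, 100, 3, dimnames = list(NULL, c("GH5", "GH13", "PL1")))
  prof[1:4, "GH5"] <- 1
  prof[1:5, "GH13"] <- 1
  prof[, "PL1"] <- 1
  expect_equal(rare_families(prof, 0.05), "GH5")
  expect_equal(rare_families(prof, 0), character(0))
  expect_error(rare_families(prof[0, , drop = FALSE]), "empty")
})

test_that("multi-modularity counts order-insensitive module multisets", {
  calls <- call_consensus(rbind(
    make_hits("g1", hmmer = c("GH5", "CBM6")),
    make_hits("g2", hmmer = c("CBM6", "GH5")),
    make_hits("g3", hmmer = c("GH10", "CBM2", "CBM2")),
    make_hits("g4", hmmer = "GH13")))
  mm <- multimodularity(calls)
  expect_equal(mm$n_multimodular, 3L)
  expect_equal(mm$unique_combinations, 2L)  # {GH5,CBM6} and {GH10,CBM2x2}
  uni <- multimodularity(call_consensus(make_hits("g1", hmmer = "GH5")))
  expect_equal(uni$n_multimodular, 0L)
})

test_that("genome summary computes coding frequencies and the 2% trend", {
  # 2 GH genes in 100 proteins: exactly 2% goes to the low trend T2
  calls <- fake_calls(2)
  s <- genome_summary("G", calls, n_proteins = 100)
  expect_equal(s$gh_cbm_frequency, 2)
  expect_equal(s$trend, "T2")
  s2 <- genome_summary("G", fake_calls(3), n_proteins = 100)
  expect_equal(s2$trend, "T1")
  expect_equal(s2$coding_frequency, 3)
  expect_warning(genome_summary("G", calls, n_proteins = 100,
                                n_genes_seen = 99), "differs")
})

test_that("Spearman correlation matches cor.test on both code paths", {
  # monotone identity and reversal
  expect_equal(gh_cbm_correlation(1:12, (1:12)^2)$rho, 1)
  expect_equal(gh_cbm_correlation(1:12, rev(1:12))$rho, -1)
  expect_true(is.na(gh_cbm_correlation(rep(3, 5), 1:5)$rho))
  # n >= 10: t approximation agrees with cor.test
  set.seed(5)
  gh <- sample(5:50, 12); cbm <- gh + round(rnorm(12, 0, 8))
  got <- gh_cbm_correlation(gh, cbm)
  ref <- suppressWarnings(stats::cor.test(gh, cbm, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  # n < 10, tie-free: exact permutation equals cor.test's exact p
  gh2 <- c(3, 9, 1, 7, 5, 8)
  cbm2 <- c(2, 8, 3, 9, 4, 7)
  got2 <- gh_cbm_correlation(gh2, cbm2)
  ref2 <- stats::cor.test(gh2, cbm2, method = "spearman", exact = TRUE)
  expect_equal(got2$rho, unname(ref2$estimate), tolerance = 1e-12)
  expect_equal(got2$p, ref2$p.value, tolerance = 1e-12)
  expect_equal(got2$method, "exact permutation")
})
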
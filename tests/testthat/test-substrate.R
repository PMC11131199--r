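map_fixture <- function() {
  data.frame(
    family_label = c("GH5", "GH118", "GH13", "PL9"),
    biomass_category = c("plant", "algal", "plant", "plant"),
    substrate_category = c("lignocellulose", "algal polysaccharides",
                           "glucans", "pectin"),
    stringsAsFactors = FALSE)
}

test_that("substrate lookup is subfamily-first with family fallback", {
  calls <- call_consensus(rbind(
    make_hits("g1", hmmer = "GH5_2"),       # falls back to GH5
    make_hits("g2", hmmer = "GH118"),
    make_hits("g3", hmmer = "CE1"),         # not GH/PL: ignored
    make_hits("g4", hmmer = "GH999")))      # unmapped
  subs <- assign_substrates(calls, map_fixture())
  expect_equal(subs$gene_id, c("g1", "g2", "g4"))
  expect_equal(subs$substrate_category,
               c("lignocellulose", "algal polysaccharides", "unassigned"))
  # subfamily entry wins over its parent family when both exist
  map2 <- rbind(map_fixture(),
                data.frame(family_label = "GH5_2",
                           biomass_category = "algal",
                           substrate_category = "algal polysaccharides"))
  subs2 <- assign_substrates(calls, map2)
  expect_equal(subs2$substrate_category[subs2$gene_id == "g1"],
               "algal polysaccharides")
  dup <- rbind(map_fixture(), map_fixture()[1, ])
  expect_error(assign_substrates(calls, dup), "duplicate")
})

test_that("assigned ratio counts modules, with empty denominator missing", {
  calls <- call_consensus(do.call(rbind, c(
    lapply(1:8, function(i) make_hits(paste0("m", i), hmmer = "GH5")),
    lapply(9:10, function(i) make_hits(paste0("m", i), hmmer = "GH999")))))
  subs <- assign_substrates(calls, map_fixture())
  expect_equal(assigned_ratio(subs), 0.8)
  all_mapped <- assign_substrates(call_consensus(
    make_hits("g1", hmmer = c("GH5", "PL9"))), map_fixture())
  expect_equal(assigned_ratio(all_mapped), 1.0)
  none <- assign_substrates(call_consensus(make_hits("g1", hmmer = "CE1")),
                            map_fixture())
  expect_true(is.na(assigned_ratio(none)))
  # a bifunctional protein contributes one module per domain
  bif <- assign_substrates(call_consensus(
    make_hits("g1", hmmer = c("GH5", "GH999"))), map_fixture())
  expect_equal(assigned_ratio(bif), 0.5)
})

test_that("secretion ratios count genes and shrink as sp_types shrink", {
  calls <- call_consensus(do.call(rbind, lapply(1:4, function(i) {
    make_hits(paste0("g", i), hmmer = "GH5")
  })))
  subs <- assign_substrates(calls, map_fixture())
  sp <- data.frame(gene_id = paste0("g", 1:4),
                   sp_type = c("SP", "LIPO", "TAT", "NONE"),
                   probability = 0.9, stringsAsFactors = FALSE)
  expect_equal(secretion_ratio(subs, sp, "lignocellulose"), 0.75)
  expect_equal(secretion_ratio(subs, sp, "lignocellulose",
                               sp_types = c("SP", "TAT")), 0.5)
  expect_equal(secretion_ratio(subs, sp, "lignocellulose",
                               sp_types = "PILIN"), 0)
  expect_true(is.na(secretion_ratio(subs, sp, "pectin")))
  # set monotonicity on random fixtures
  set.seed(3)
  for (i in 1:20) {
    types <- sample(c("SP", "LIPO", "TAT", "NONE"), 4, replace = TRUE)
    sp$sp_type <- types
    full <- secretion_ratio(subs, sp, "lignocellulose")
    subset_ <- secretion_ratio(subs, sp, "lignocellulose",
                               sp_types = c("SP", "TAT"))
    expect_true(subset_ <= full)
  }
})

test_that("substrate profile bundles counts and ratios per genome", {
  calls <- call_consensus(rbind(make_hits("g1", hmmer = "GH5"),
                                make_hits("g2", hmmer = "GH118"),
                                make_hits("g3", hmmer = "GH999")))
  subs <- assign_substrates(calls, map_fixture())
  sp <- data.frame(gene_id = c("g1", "g2", "g3"),
                   sp_type = c("SP", "NONE", "SP"), probability = 0.9,
                   stringsAsFactors = FALSE)
  prof <- substrate_profile("G1", subs, sp)
  expect_equal(prof$n_lignocellulose, 1L)
  expect_equal(prof$n_algal_polysaccharides, 1L)
  expect_equal(prof$n_unassigned, 1L)
  expect_equal(prof$assigned_ratio, 2 / 3)
  expect_equal(prof$secretion_ratio_any, 0.5)   # g1 yes, g2 no
})
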
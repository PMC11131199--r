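test_that("the co-localisation rule forms and rejects clusters as stated", {
  # CAZyme + auxiliary separated by two other genes: one cluster
  g <- make_contig(c("CAZYME", "OTHER", "OTHER", "AUXILIARY"))
  cgcs <- detect_cgcs(g)
  expect_equal(nrow(cgcs), 1L)
  expect_equal(cgcs$n_cazymes, 1)
  expect_equal(cgcs$n_auxiliary, 1)
  expect_equal(cgcs$n_other, 2)

  # a gap of three breaks the chain; singletons fail composition
  g2 <- make_contig(c("CAZYME", "OTHER", "OTHER", "OTHER", "CAZYME"))
  expect_equal(nrow(detect_cgcs(g2)), 0L)

  # chain covering ranks 0-3; the distant CAZyme at rank 7 is excluded
  g3 <- make_contig(c("CAZYME", "CAZYME", "OTHER", "AUXILIARY", "OTHER",
                      "OTHER", "OTHER", "CAZYME"))
  cgcs3 <- detect_cgcs(g3)
  expect_equal(span_frame(cgcs3),
               data.frame(first_rank = 0L, last_rank = 3L))
  expect_equal(cgcs3$n_cazymes, 2)
  expect_equal(cgcs3$n_auxiliary, 1)

  # two auxiliary genes without a CAZyme never cluster
  expect_equal(nrow(detect_cgcs(make_contig(c("AUXILIARY", "AUXILIARY")))),
               0L)
  expect_error(detect_cgcs(g, max_gap = -1), "max_gap")
  unsorted <- g[c(2, 1, 3, 4), ]
  expect_error(detect_cgcs(unsorted), "sorted")
})

test_that("greedy chaining equals the brute-force window oracle", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(1:50, 1)
    roles <- sample(c("CAZYME", "AUXILIARY", "OTHER"), n, replace = TRUE,
                    prob = c(0.25, 0.15, 0.6))
    mg <- sample(0:3, 1)
    got <- span_frame(detect_cgcs(make_contig(roles), max_gap = mg))
    want <- cgc_oracle(roles, mg)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("raising max_gap never loses clustered CAZymes", {
  set.seed(8)
  for (i in 1:30) {
    roles <- sample(c("CAZYME", "AUXILIARY", "OTHER"), 40, replace = TRUE,
                    prob = c(0.25, 0.15, 0.6))
    g <- make_contig(roles)
    caz_in <- vapply(0:4, function(mg) {
      cgcs <- detect_cgcs(g, max_gap = mg)
      sum(cgcs$n_cazymes)
    }, numeric(1))
    expect_true(all(diff(caz_in) >= 0))
  }
})

test_that("auxiliary role assignment follows products with CAZyme precedence", {
  genes <- make_contig(c("OTHER", "OTHER", "OTHER"))[
    , c("genome_id", "contig_id", "gene_id", "start", "end", "strand",
        "rank", "product", "aa_length")]
  genes$product <- c("ABC transporter permease", "hypothetical protein",
                     "LacI family transcriptional regulator")
  calls <- call_consensus(rbind(
    make_hits(genes$gene_id[1]),
    make_hits(genes$gene_id[2], diamond = "GH13"),
    make_hits(genes$gene_id[3], hmmer = "GH13")))
  out <- assign_auxiliary(genes, calls)
  expect_equal(out$role, c("AUXILIARY", "OTHER", "CAZYME"))
  expect_equal(out$is_hypothetical, c(FALSE, TRUE, FALSE))
  expect_equal(out$is_unclassified_cazyme, c(FALSE, TRUE, FALSE))
  expect_warning(assign_auxiliary(genes, calls,
                                  signature_config = character(0)),
                 "auxiliary")
})

test_that("co-localisation fractions count genes inside cluster spans", {
  roles <- c("CAZYME", "OTHER", "AUXILIARY", rep("OTHER", 4), "CAZYME")
  mods <- list("GH5", character(0), character(0), character(0),
               character(0), character(0), character(0), "GH13")
  hyp <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  g <- make_contig(roles, modules = mods, hypothetical = hyp)
  cgcs <- detect_cgcs_genome(g)
  fr <- cgc_fractions(g, cgcs)
  expect_equal(fr$frac_cazymes_in_cgc, 0.5)     # 1 of 2 inside the span
  expect_equal(fr$frac_gh_in_cgc, 0.5)
  expect_equal(fr$frac_hypothetical_in_cgc, 1 / 3)
  expect_equal(fr$frac_unassigned_in_cgc, 1 / 3) # the rank-1 OTHER gene

  # all CAZymes clustered -> 1; no cluster -> 0; no CAZymes -> NA
  g_all <- make_contig(c("CAZYME", "CAZYME"),
                       modules = list("GH5", "GH13"))
  expect_equal(cgc_fractions(g_all,
                             detect_cgcs_genome(g_all))$frac_cazymes_in_cgc,
               1)
  g_none <- make_contig(c("CAZYME", rep("OTHER", 5), "CAZYME"),
                        modules = list("GH5", character(0), character(0),
                                       character(0), character(0),
                                       character(0), "GH13"))
  expect_equal(cgc_fractions(g_none,
                             detect_cgcs_genome(g_none))$frac_cazymes_in_cgc,
               0)
  g_empty <- make_contig(c("OTHER", "OTHER"))
  expect_true(is.na(cgc_fractions(g_empty,
    detect_cgcs_genome(g_empty))$frac_cazymes_in_cgc))
})

test_that("fixture with four GH genes, two clustered, gives frac_gh 0.5", {
  roles <- c("CAZYME", "CAZYME", rep("OTHER", 4), "CAZYME",
             rep("OTHER", 4), "CAZYME")
  mods <- lapply(roles, function(r) if (r == "CAZYME") "GH5" else
    character(0))
  g <- make_contig(roles, modules = mods)
  cgcs <- detect_cgcs_genome(g)
  expect_equal(nrow(cgcs), 1L)  # only the adjacent pair clusters
  expect_equal(cgc_fractions(g, cgcs)$frac_gh_in_cgc, 0.5)
})
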
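test_that("CAZyme label grammar accepts the six classes and rejects others", {
  parsed <- parse_cazy_label(c("GH5_2", "CBM50", "GT2", "AA10", "PL9_1"))
  expect_equal(parsed$cazy_class, c("GH", "CBM", "GT", "AA", "PL"))
  expect_equal(parsed$family, c(5L, 50L, 2L, 10L, 9L))
  expect_equal(parsed$subfamily, c(2L, NA, NA, NA, 1L))
  expect_error(parse_cazy_label("XYZ9"), "invalid")
  expect_error(parse_cazy_label("GH"), "invalid")
  expect_false(is_cazy_label("gh5"))
  expect_equal(family_label(c("GH5_2", "CBM50")), c("GH5", "CBM50"))
})

write_gff_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gff",
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("read_gff assigns per-contig ranks by start with deterministic ties", {
  path <- write_gff_lines(c(
    "c1\tp\tCDS\t900\t1400\t.\t+\t0\tID=g3;product=x",
    "c1\tp\tCDS\t10\t300\t.\t+\t0\tID=g1;product=x",
    "c1\tp\tCDS\t500\t800\t.\t-\t0\tID=g2;product=x",
    "c2\tp\tCDS\t100\t200\t.\t+\t0\tID=h1;product=x",
    "c2\tp\tCDS\t400\t500\t.\t+\t0\tID=h2;product=x"))
  g <- read_gff(path, genome_id = "G")
  expect_equal(g$gene_id[g$contig_id == "c1"], c("g1", "g2", "g3"))
  expect_equal(g$rank[g$contig_id == "c1"], 0:2)
  # ranks restart per contig
  expect_equal(g$rank[g$contig_id == "c2"], 0:1)
  # ties on start broken by end then gene_id
  path2 <- write_gff_lines(c(
    "c1\tp\tCDS\t10\t900\t.\t+\t0\tID=b",
    "c1\tp\tCDS\t10\t300\t.\t+\t0\tID=a"))
  g2 <- read_gff(path2)
  expect_equal(g2$gene_id, c("a", "b"))
})

test_that("read_gff rejects malformed coordinates and duplicate ids", {
  bad <- write_gff_lines("c1\tp\tCDS\t500\t100\t.\t+\t0\tID=g1")
  expect_error(read_gff(bad), "end < start")
  dup <- write_gff_lines(c("c1\tp\tCDS\t1\t90\t.\t+\t0\tID=g1",
                           "c1\tp\tCDS\t200\t290\t.\t+\t0\tID=g1"))
  expect_error(read_gff(dup), "duplicate")
  empty <- withr::local_tempfile(fileext = ".gff")
  writeLines("##gff-version 3", empty)
  expect_warning(g <- read_gff(empty), "no CDS")
  expect_equal(nrow(g), 0L)
})

test_that("read_dbcan_overview maps tool fields and splits '+' labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GeneID\tHMMER\tHotpep\tDIAMOND\t#ofTools",
               "g1\t-\tGH13\tGH13\t2",
               "g2\tGH5_2+CBM6\t-\tGH5\t2"), path)
  ov <- read_dbcan_overview(path)
  expect_equal(ov$hmmer[[1]], character(0))
  expect_equal(ov$hotpep[[1]], "GH13")
  expect_equal(ov$hmmer[[2]], c("GH5_2", "CBM6"))
  # grammar violations: fail by default, skip on request
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GeneID\tHMMER\tHotpep\tDIAMOND\t#ofTools",
               "g1\tXYZ9\t-\t-\t1",
               "g2\tGH13\t-\t-\t1"), bad)
  expect_error(read_dbcan_overview(bad), "g1")
  expect_warning(ov2 <- read_dbcan_overview(bad, on_bad_label = "skip"),
                 "g1")
  expect_equal(ov2$gene_id, "g2")
  # wrong layout rejected, not guessed
  wrong <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\thits", "g1\tGH13"), wrong)
  expect_error(read_dbcan_overview(wrong), "overview")
})

test_that("signalP, outfmt6 and metadata readers validate ranges", {
  sp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsp_type\tprobability", "g1\tSP\t0.98",
               "g2\tNONE\t0.6"), sp)
  calls <- read_signalp(sp)
  expect_equal(calls$sp_type, c("SP", "NONE"))
  bad_sp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsp_type\tprobability", "g1\tSP\t1.2"), bad_sp)
  expect_error(read_signalp(bad_sp), "\\[0,1\\]")

  o6 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t101.0\t200\t10\t1\t1\t200\t1\t200\t1e-50\t300", o6)
  expect_error(read_outfmt6(o6), "identity")

  meta <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste("genome_id", "class", "order", "family", "habitat",
               "completeness", "contamination", "genome_size_bp",
               "n_proteins", sep = "\t")
  writeLines(c(hdr, paste("G1", "c", "o", "f", "marine", "80.5", "9.9",
                          "4000000", "3500", sep = "\t")), meta)
  m <- read_metadata(meta)
  expect_equal(m$contamination, 9.9)   # below-10 boundary region round-trips
  writeLines(c(hdr, paste("G1", "c", "o", "f", "marine", "100.5", "1",
                          "4000000", "3500", sep = "\t")), meta)
  expect_error(read_metadata(meta), "completeness")
})

test_that("gene and overview tables round-trip through their writers", {
  cfg <- sim_config(seed = 11, groups = c(a = 1L),
                    genes_per_genome = c(300L, 400L))
  b <- generate_dataset(cfg)
  genes <- b$genes[[1]]
  path <- withr::local_tempfile(fileext = ".gff")
  write_gff(genes, path)
  back <- read_gff(path, genome_id = genes$genome_id[1])
  rownames(back) <- NULL
  expect_equal(back, genes)
  ov <- b$overview[[1]]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_dbcan_overview(ov, path2)
  back2 <- read_dbcan_overview(path2)
  expect_equal(back2, ov)
})
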
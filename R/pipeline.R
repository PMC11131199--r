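#' Pipeline configuration
#'
#' Collects every input path and every analysis threshold in one place so
#' defaults are configuration, never hard-coded in stage logic. The
#' defaults are the conventional ones for medium-to-high quality draft
#' genomes: completeness above 75\%, contamination below 10\%, at least
#' 10 classified CAZymes per genome, taxon classes with fewer than 10
#' genomes pooled as "other class", rare families below 5\% occupancy,
#' T1/T2 coding-frequency trend split at 2\%, novelty flag below 30\%
#' identity, Kruskal-Wallis screen at 0.05, log10 LDA score threshold 4,
#' 999 permutations. A seed is mandatory whenever permutation tests run.
#'
#' @param bundle_dir directory holding `gff/`, `dbcan/`, `signalp.tsv`,
#'   `outfmt6.tsv`, `metadata.tsv`, `substrate_map.tsv` (the layout
#'   written by [generate_dataset()]).
#' @param outdir output directory for the report bundle.
#' @param max_gap CGC chaining gap (default 2).
#' @param min_completeness,max_contamination,min_cazymes quality filter
#'   thresholds.
#' @param min_class_size small-class pooling threshold.
#' @param rare_threshold rare-family occupancy threshold.
#' @param trend_threshold T1/T2 split, percent.
#' @param novelty_threshold low-identity flag, percent.
#' @param kw_alpha,lda_threshold enrichment screen and LDA flag levels.
#' @param n_permutations permutations for PERMANOVA/ANOSIM.
#' @param granularity profile matrix granularity.
#' @param group_by metadata column defining comparison groups.
#' @param seed RNG seed (hard error if missing while permutations are
#'   requested).
#' @return config list (class `cazyome_pipeline_config`).
#' @export
pipeline_config <- function(bundle_dir, outdir,
                            max_gap = 2L,
                            min_completeness = 75,
                            max_contamination = 10,
                            min_cazymes = 10L,
                            min_class_size = 10L,
                            rare_threshold = 0.05,
                            trend_threshold = 2,
                            novelty_threshold = 30,
                            kw_alpha = 0.05,
                            lda_threshold = 4,
                            n_permutations = 999L,
                            granularity = c("family", "subfamily"),
                            group_by = "class",
                            seed = NULL) {
  if (n_permutations > 0 && is.null(seed)) {
    stop("seed is mandatory when permutation tests are requested")
  }
  cfg <- list(bundle_dir = bundle_dir, outdir = outdir,
              max_gap = as.integer(max_gap),
              min_completeness = min_completeness,
              max_contamination = max_contamination,
              min_cazymes = as.integer(min_cazymes),
              min_class_size = as.integer(min_class_size),
              rare_threshold = rare_threshold,
              trend_threshold = trend_threshold,
              novelty_threshold = novelty_threshold,
              kw_alpha = kw_alpha, lda_threshold = lda_threshold,
              n_permutations = as.integer(n_permutations),
              granularity = match.arg(granularity),
              group_by = group_by, seed = seed)
  class(cfg) <- "cazyome_pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full comparative CAZyome pipeline
#'
#' Stage order: read inputs, per-gene consensus calling, quality
#' filtering, small-class grouping, role assignment and CGC detection,
#' substrate annotation and secretion ratios, per-genome metrics, profile
#' matrix and Jaccard distances, ordination and group statistics
#' (PCoA, PERMANOVA, ANOSIM, enrichment, LDA effect size), novelty
#' scoring, report. Every stage writes its TSV into `outdir` and appends
#' a line with counts to `run_log.txt`; the config is echoed to
#' `config.yaml` for provenance. A genome whose inputs fail to parse is
#' quarantined (dropped with a logged reason) rather than aborting the
#' run, unless more than 10\% of genomes fail. A missing `signalp.tsv`
#' skips the secretion stage with an explicit "missing input" status and
#' leaves all other outputs unchanged.
#'
#' @param config [pipeline_config()] object.
#' @return invisible list with the main in-memory results (calls,
#'   cgcs, summaries, profile, distances, ordination, group tests,
#'   enrichment, novelty, stage log).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cazyome_pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run_log.txt")
  cat("", file = log_path)  # truncate
  logline <- function(...) {
    cat(paste0(paste0(...), "\n"), file = log_path, append = TRUE)
  }
  cfg_echo <- config
  class(cfg_echo) <- NULL
  yaml::write_yaml(cfg_echo, file.path(config$outdir, "config.yaml"))

  # ---- stage: read ----
  metadata <- read_metadata(file.path(config$bundle_dir, "metadata.tsv"))
  map <- read_substrate_map(file.path(config$bundle_dir,
                                      "substrate_map.tsv"))
  gff_files <- sort(list.files(file.path(config$bundle_dir, "gff"),
                               pattern = "\\.gff$", full.names = TRUE))
  genome_ids <- sub("\\.gff$", "", basename(gff_files))
  genes <- list(); overview <- list(); failed <- character(0)
  for (i in seq_along(genome_ids)) {
    gid <- genome_ids[i]
    res <- tryCatch({
      g <- read_gff(gff_files[i], genome_id = gid)
      ov_path <- file.path(config$bundle_dir, "dbcan",
                           paste0(gid, ".tsv"))
      ov <- if (file.exists(ov_path)) read_dbcan_overview(ov_path) else
        data.frame(gene_id = character(0))
      list(genes = g, overview = ov)
    }, error = function(e) {
      logline("quarantined ", gid, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, gid) else {
      genes[[gid]] <- res$genes
      overview[[gid]] <- res$overview
    }
  }
  if (length(failed) > 0.1 * length(genome_ids)) {
    stop("more than 10% of genomes failed to parse: ",
         paste(failed, collapse = ", "))
  }
  logline("read: ", length(genes), " genomes, ", length(failed),
          " quarantined")

  # ---- stage: consensus ----
  calls <- lapply(overview, function(ov) {
    if (nrow(ov) == 0L) {
      return(data.frame(gene_id = character(0), status = character(0),
                        modules = I(list()), n_modules = integer(0),
                        tools = I(list())))
    }
    call_consensus(ov)
  })
  calls_out <- do.call(rbind, c(mapply(function(gid, cl) {
    if (nrow(cl) == 0L) return(NULL)
    cbind(genome_id = gid, cl, stringsAsFactors = FALSE)
  }, names(calls), calls, SIMPLIFY = FALSE), list(make.row.names = FALSE)))
  write_tsv(calls_out, file.path(config$outdir, "consensus_calls.tsv"))
  logline("consensus: ", sum(calls_out$status == "classified"),
          " classified, ", sum(calls_out$status == "unclassified"),
          " unclassified")

  # ---- stage: quality filter + class grouping ----
  metadata <- metadata[metadata$genome_id %in% names(genes), , drop = FALSE]
  qf <- quality_filter(metadata, calls,
                       min_completeness = config$min_completeness,
                       max_contamination = config$max_contamination,
                       min_cazymes = config$min_cazymes)
  write_tsv(qf$log, file.path(config$outdir, "quality_filter.tsv"))
  keep <- qf$retained
  metadata <- metadata[metadata$genome_id %in% keep, , drop = FALSE]
  metadata <- group_small_classes(metadata, min_n = config$min_class_size)
  genes <- genes[keep]; calls <- calls[keep]
  logline("quality filter: ", length(keep), " genomes retained")

  # ---- stage: roles + CGC ----
  roles <- mapply(function(g, cl) assign_auxiliary(g, cl),
                  genes, calls, SIMPLIFY = FALSE)
  cgcs <- lapply(roles, detect_cgcs_genome, max_gap = config$max_gap)
  cgc_all <- do.call(rbind, c(cgcs, list(make.row.names = FALSE)))
  write_cgcs(cgc_all, file.path(config$outdir, "cgcs.tsv"),
             file.path(config$outdir, "cgcs.bed"))
  fractions <- do.call(rbind, c(mapply(cgc_fractions, roles, cgcs,
                                       SIMPLIFY = FALSE),
                                list(make.row.names = FALSE)))
  write_tsv(fractions, file.path(config$outdir, "cgc_fractions.tsv"))
  logline("cgc: ", nrow(cgc_all), " clusters in ", length(cgcs),
          " genomes")

  # ---- stage: substrates + secretion ----
  substrates <- lapply(calls, assign_substrates, map = map)
  sp_path <- file.path(config$bundle_dir, "signalp.tsv")
  if (file.exists(sp_path)) {
    sp_calls <- read_signalp(sp_path)
    profiles <- do.call(rbind, c(mapply(function(gid, s) {
      substrate_profile(gid, s, sp_calls)
    }, names(substrates), substrates, SIMPLIFY = FALSE),
    list(make.row.names = FALSE)))
    write_tsv(profiles, file.path(config$outdir,
                                  "substrate_profiles.tsv"))
    logline("secretion: profiles for ", nrow(profiles), " genomes")
  } else {
    profiles <- NULL
    counts <- do.call(rbind, c(mapply(function(gid, s) {
      out <- data.frame(genome_id = gid, stringsAsFactors = FALSE)
      cnt <- substrate_counts(s)
      for (cat in names(cnt)) {
        out[[paste0("n_", gsub("[ /-]", "_", cat))]] <-
          as.integer(cnt[[cat]])
      }
      out$assigned_ratio <- assigned_ratio(s)
      out
    }, names(substrates), substrates, SIMPLIFY = FALSE),
    list(make.row.names = FALSE)))
    write_tsv(counts, file.path(config$outdir, "substrate_profiles.tsv"))
    logline("secretion: skipped (missing input ", sp_path, ")")
  }

  # ---- stage: per-genome metrics ----
  summaries <- do.call(rbind, c(mapply(function(gid, cl) {
    genome_summary(gid, cl,
                   n_proteins = metadata$n_proteins[
                     metadata$genome_id == gid],
                   trend_threshold = config$trend_threshold)
  }, names(calls), calls, SIMPLIFY = FALSE),
  list(make.row.names = FALSE)))
  write_tsv(summaries, file.path(config$outdir, "genome_summaries.tsv"))
  groups <- metadata[[config$group_by]][
    match(summaries$genome_id, metadata$genome_id)]
  aggregates <- taxon_aggregate(summaries, groups)
  write_tsv(aggregates, file.path(config$outdir, "taxon_aggregates.tsv"))
  logline("metrics: ", nrow(summaries), " genome summaries")

  # ---- stage: matrices + comparative statistics ----
  profile <- profile_matrix(calls, values = "presence",
                            granularity = config$granularity)
  rare <- rare_families(profile, threshold = config$rare_threshold)
  writeLines(rare, file.path(config$outdir, "rare_families.txt"))
  d <- jaccard_matrix(profile)
  write_tsv(cbind(data.frame(genome_id = rownames(d)), as.data.frame(d)),
            file.path(config$outdir, "jaccard_distances.tsv"))
  ord <- pcoa(d)
  coords <- as.data.frame(ord$coordinates[, seq_len(min(3,
    ncol(ord$coordinates))), drop = FALSE])
  write_tsv(cbind(data.frame(genome_id = rownames(d)), coords),
            file.path(config$outdir, "pcoa_coordinates.tsv"))
  stats_res <- list()
  group_sizes <- table(groups)
  if (length(group_sizes) >= 2L && all(group_sizes >= 2L)) {
    stats_res$permanova <- permanova(d, groups,
                                     n_permutations = config$n_permutations,
                                     seed = config$seed)
    stats_res$anosim <- anosim(d, groups,
                               n_permutations = config$n_permutations,
                               seed = config$seed)
    enr <- if (length(group_sizes) == 2L) {
      lda_effect_size(profile, groups, kw_alpha = config$kw_alpha,
                      lda_threshold = config$lda_threshold,
                      seed = config$seed)
    } else {
      kw_enrichment(profile, groups, alpha = config$kw_alpha)
    }
    write_tsv(enr, file.path(config$outdir, "enrichment.tsv"))
    stats_res$n_significant <- sum(enr$significant)
    logline("stats: PERMANOVA F=", signif(stats_res$permanova$statistic, 4),
            " p=", stats_res$permanova$p,
            "; ANOSIM R=", signif(stats_res$anosim$statistic, 4),
            " p=", stats_res$anosim$p)
  } else {
    enr <- NULL
    logline("stats: skipped (need >= 2 groups with >= 2 genomes)")
  }
  jsonlite::write_json(
    list(permanova = stats_res$permanova, anosim = stats_res$anosim,
         eigenvalues = ord$eigenvalues,
         proportion_explained = ord$proportion_explained),
    file.path(config$outdir, "group_stats.json"),
    auto_unbox = TRUE, digits = NA, null = "null")

  # ---- stage: novelty ----
  o6_path <- file.path(config$bundle_dir, "outfmt6.tsv")
  novelty <- NULL
  if (file.exists(o6_path)) {
    hits <- read_outfmt6(o6_path)
    classified_ids <- calls_out$gene_id[
      calls_out$status == "classified" & calls_out$genome_id %in% keep]
    records <- best_hits(hits[hits$qseqid %in% classified_ids, ,
                              drop = FALSE],
                         query_ids = classified_ids,
                         low_identity = config$novelty_threshold)
    genome_of <- calls_out$genome_id[match(records$gene_id,
                                           calls_out$gene_id)]
    novelty <- novelty_summary(records,
                               grouping = groups[match(genome_of,
                                 summaries$genome_id)],
                               low_identity = config$novelty_threshold)
    write_tsv(novelty, file.path(config$outdir, "novelty_summary.tsv"))
    logline("novelty: ", nrow(records), " best-hit records")
  } else {
    logline("novelty: skipped (missing input ", o6_path, ")")
  }
  logline("done")
  invisible(list(metadata = metadata, calls = calls, cgcs = cgc_all,
                 cgc_fractions = fractions, substrate_profiles = profiles,
                 summaries = summaries, aggregates = aggregates,
                 profile = profile, distances = d, ordination = ord,
                 stats = stats_res, enrichment = enr, novelty = novelty,
                 rare_families = rare, quarantined = failed))
}
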
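#' Default CAZyme family universe for simulations
#'
#' A realistic label universe spanning all six module classes, including a
#' few subfamily-granular labels (e.g. GH5_2) so family-level collapsing
#' is exercised, and a handful of GH families deliberately absent from
#' [default_substrate_map()] so assigned ratios fall below 1.
#'
#' @return data.frame `label`, `cazy_class`.
#' @export
default_family_universe <- function() {
  gh <- c("GH1", "GH2", "GH3", "GH4", "GH5_2", "GH5_46", "GH6", "GH8",
          "GH9", "GH10", "GH11", "GH13_10", "GH13_31", "GH15", "GH16",
          "GH18", "GH19", "GH20", "GH23", "GH26", "GH28", "GH29", "GH30",
          "GH31", "GH33", "GH35", "GH36", "GH38", "GH39", "GH42", "GH43_4",
          "GH44", "GH45", "GH48", "GH50", "GH51", "GH53", "GH54", "GH57",
          "GH62", "GH65", "GH67", "GH73", "GH74", "GH77", "GH78", "GH81",
          "GH95", "GH102", "GH103", "GH105", "GH107", "GH109", "GH115",
          "GH118", "GH139", "GH141", "GH151", "GH168")
  pl <- c("PL1", "PL6", "PL7", "PL8", "PL9", "PL11", "PL12", "PL17", "PL22")
  ce <- c("CE1", "CE2", "CE3", "CE4", "CE6", "CE7", "CE8", "CE11")
  aa <- c("AA1", "AA2", "AA3", "AA6", "AA10", "AA12")
  cbm <- c("CBM2", "CBM4", "CBM6", "CBM9", "CBM13", "CBM16", "CBM32",
           "CBM35", "CBM44", "CBM47", "CBM48", "CBM50", "CBM51", "CBM57",
           "CBM66", "CBM67")
  labels <- c(gh, pl, ce, aa, cbm)
  data.frame(label = labels, cazy_class = cazy_class_of(labels),
             stringsAsFactors = FALSE)
}

# sample() without the scalar-x surprise
sample_from <- function(v, n = 1L, replace = FALSE) {
  v[sample.int(length(v), n, replace = replace)]
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic
#' annotated-genome generator. Per-group family occurrence probabilities
#' are spelled per CAZyme class (`class_probs`); planted enrichments
#' override the occurrence probability of single families in single
#' groups. Planted CAZyme gene clusters are flanked by at least
#' `flank_gap` non-signature genes (`flank_gap > max_gap` is enforced so
#' planted clusters are unambiguous), and background CAZymes are placed
#' isolated (pairwise more than `max_gap` genes apart) so the planted
#' spans are exactly the true clusters.
#'
#' @param seed integer RNG seed.
#' @param groups named integer vector: genomes per simulated taxon group.
#' @param genes_per_genome length-2 integer range of protein-coding genes.
#' @param n_contigs contigs per genome (genes split evenly).
#' @param family_universe data.frame `label`, `cazy_class`.
#' @param class_probs named list (one entry per group) of named numeric
#'   vectors giving the per-family occurrence probability for each CAZyme
#'   class, e.g. `list(g1 = c(GH = 0.7, PL = 0.3, ...), ...)`.
#' @param planted_enrichments `NULL` or data.frame `family`,
#'   `high_group`, `occupancy_high`, `occupancy_low`.
#' @param cgc_per_genome planted clusters per genome.
#' @param cgc_cazymes,cgc_auxiliary ranges (length-2) for cluster
#'   composition.
#' @param max_gap clustering gap the dataset is built for.
#' @param flank_gap minimum clear flank around planted clusters; must
#'   exceed `max_gap`.
#' @param frac_multimodular fraction of classified CAZymes given extra
#'   modules.
#' @param frac_unclassified target fraction of unclassified CAZymes among
#'   CAZyme-like genes (emitted as DIAMOND-only rows).
#' @param n_gt_genes glycosyltransferase-only genes per genome.
#' @param sp_prob named signal-peptide probability per substrate category
#'   (names from [substrate_categories] plus `unassigned` and `background`
#'   for non-GH/PL genes).
#' @param completeness,contamination length-2 uniform ranges for the
#'   metadata quality columns.
#' @param habitats character vector sampled uniformly per genome.
#' @param substrate_map map emitted with the bundle.
#' @return validated config (list, class `cazyome_sim_config`).
#' @export
sim_config <- function(seed = 1L,
                       groups = c(group_a = 30L, group_b = 30L),
                       genes_per_genome = c(800L, 1200L),
                       n_contigs = 2L,
                       family_universe = default_family_universe(),
                       class_probs = NULL,
                       planted_enrichments = NULL,
                       cgc_per_genome = 2L,
                       cgc_cazymes = c(2L, 3L),
                       cgc_auxiliary = c(1L, 2L),
                       max_gap = 2L,
                       flank_gap = 3L,
                       frac_multimodular = 0.1,
                       frac_unclassified = 0.03,
                       n_gt_genes = 2L,
                       sp_prob = NULL,
                       completeness = c(76, 100),
                       contamination = c(0, 9.9),
                       habitats = c("marine", "freshwater", "wastewater",
                                    "AD reactor", "terrestrial"),
                       substrate_map = default_substrate_map()) {
  if (is.null(class_probs)) {
    base <- c(GH = 0.35, PL = 0.25, CE = 0.4, AA = 0.15, CBM = 0.3)
    class_probs <- stats::setNames(rep(list(base), length(groups)),
                                   names(groups))
  }
  if (is.null(sp_prob)) {
    sp_prob <- c("algal polysaccharides" = 0.7, glucans = 0.3,
                 oligosaccharides = 0.5, lignocellulose = 0.76,
                 "NAG-based" = 0.5, pectin = 0.84, other = 0.5,
                 unassigned = 0.5, background = 0.08)
  }
  cfg <- list(seed = as.integer(seed), groups = groups,
              genes_per_genome = genes_per_genome, n_contigs = n_contigs,
              family_universe = family_universe, class_probs = class_probs,
              planted_enrichments = planted_enrichments,
              cgc_per_genome = cgc_per_genome, cgc_cazymes = cgc_cazymes,
              cgc_auxiliary = cgc_auxiliary, max_gap = max_gap,
              flank_gap = flank_gap, frac_multimodular = frac_multimodular,
              frac_unclassified = frac_unclassified,
              n_gt_genes = n_gt_genes, sp_prob = sp_prob,
              completeness = completeness, contamination = contamination,
              habitats = habitats, substrate_map = substrate_map)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$groups) >= 1L, all(cfg$groups >= 1L),
            !is.null(names(cfg$groups)))
  if (cfg$flank_gap <= cfg$max_gap) {
    stop("flank_gap must exceed max_gap so planted clusters are unambiguous")
  }
  probs <- unlist(cfg$class_probs)
  if (any(probs < 0 | probs > 1)) stop("class_probs must lie in [0,1]")
  if (!setequal(names(cfg$class_probs), names(cfg$groups))) {
    stop("class_probs must name every group")
  }
  if (cfg$frac_unclassified < 0 || cfg$frac_unclassified >= 1 ||
      cfg$frac_multimodular < 0 || cfg$frac_multimodular > 1) {
    stop("fractions must lie in [0,1)")
  }
  if (!is.null(cfg$planted_enrichments)) {
    pe <- cfg$planted_enrichments
    stopifnot(all(c("family", "high_group", "occupancy_high",
                    "occupancy_low") %in% names(pe)))
    if (!all(pe$family %in% cfg$family_universe$label)) {
      stop("planted enrichment family not in universe")
    }
    if (!all(pe$high_group %in% names(cfg$groups))) {
      stop("planted enrichment group unknown")
    }
    if (any(pe$occupancy_high < 0 | pe$occupancy_high > 1 |
            pe$occupancy_low < 0 | pe$occupancy_low > 1)) {
      stop("occupancies must lie in [0,1]")
    }
  }
  # feasibility: worst-case cluster footprint must fit a contig
  max_span <- max(cfg$cgc_cazymes) + max(cfg$cgc_auxiliary)
  footprint <- cfg$cgc_per_genome *
    (max_span + (max_span - 1) * cfg$max_gap + 2 * cfg$flank_gap + 2)
  if (footprint > min(cfg$genes_per_genome)) {
    stop("planted clusters do not fit the smallest genome")
  }
  class(cfg) <- "cazyome_sim_config"
  cfg
}

# per-family occurrence probability matrix (families x groups)
occurrence_matrix <- function(cfg) {
  fams <- cfg$family_universe
  occ <- sapply(names(cfg$groups), function(g) {
    unname(cfg$class_probs[[g]][fams$cazy_class])
  })
  occ <- matrix(occ, nrow = nrow(fams),
                dimnames = list(fams$label, names(cfg$groups)))
  if (!is.null(cfg$planted_enrichments)) {
    for (i in seq_len(nrow(cfg$planted_enrichments))) {
      pe <- cfg$planted_enrichments[i, ]
      occ[pe$family, ] <- pe$occupancy_low
      occ[pe$family, pe$high_group] <- pe$occupancy_high
    }
  }
  occ
}

#' Simulate only the genomes x families presence matrix
#'
#' Fast path drawing family presence from the same occurrence model as
#' [generate_dataset()] without constructing gene-level tables; used for
#' statistical calibration at scale (null distributions, enrichment
#' recovery).
#'
#' @param config [sim_config()] object.
#' @return list `profile` (binary matrix), `groups` (label per genome),
#'   `enriched_families`.
#' @export
simulate_profile_matrix <- function(config) {
  occ <- occurrence_matrix(config)
  genome_group <- rep(names(config$groups), config$groups)
  genome_ids <- sprintf("sim%03d", seq_along(genome_group))
  profile <- withr::with_seed(config$seed, {
    t(vapply(genome_group, function(g) {
      stats::rbinom(nrow(occ), 1L, occ[, g])
    }, integer(nrow(occ))))
  })
  dimnames(profile) <- list(genome_ids, rownames(occ))
  list(profile = profile, groups = genome_group,
       enriched_families = config$planted_enrichments$family)
}

#' @rdname simulate_profile_matrix
#' @export
simulate_null_profile <- function(config) {
  simulate_profile_matrix(null_config(config))
}

null_config <- function(config) {
  config$planted_enrichments <- NULL
  config$class_probs <- stats::setNames(
    rep(config$class_probs[1L], length(config$groups)), names(config$groups))
  validate_sim_config(unclass(config))
}

#' Generate a complete synthetic annotated-genome bundle
#'
#' Emits, per genome, a prodigal-style GFF3 gene table and a dbCAN2-style
#' overview table, plus dataset-wide signalP, outfmt6, metadata and
#' substrate-map tables, together with the ground truth (planted cluster
#' spans, per-gene true status and signal-peptide label, planted enriched
#' families). Deterministic under a fixed seed: the same config yields a
#' byte-identical bundle. Planted clusters are flanked and background
#' CAZymes isolated as documented in [sim_config()], so cluster detection
#' at the configured `max_gap` recovers exactly the planted spans.
#'
#' @param config [sim_config()] object.
#' @param dir optional output directory; when given, files are written as
#'   `gff/<genome>.gff`, `dbcan/<genome>.tsv`, `signalp.tsv`,
#'   `outfmt6.tsv`, `metadata.tsv`, `substrate_map.tsv`,
#'   `ground_truth.json`.
#' @return a list with in-memory components `genes` (named list of gene
#'   tables), `overview` (named list), `signalp`, `outfmt6`, `metadata`,
#'   `substrate_map` and `ground_truth`; invisibly when `dir` is given.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cazyome_sim_config"))
  occ <- occurrence_matrix(config)
  genome_group <- rep(names(config$groups), config$groups)
  genome_ids <- sprintf("sim%03d", seq_along(genome_group))
  bundle <- withr::with_seed(config$seed, {
    genomes <- vector("list", length(genome_ids))
    for (i in seq_along(genome_ids)) {
      present <- rownames(occ)[stats::rbinom(nrow(occ), 1L,
                                             occ[, genome_group[i]]) == 1L]
      genomes[[i]] <- simulate_genome(config, genome_ids[i], present)
    }
    names(genomes) <- genome_ids
    assemble_bundle(config, genomes, genome_ids, genome_group)
  })
  if (!is.null(dir)) {
    write_bundle(bundle, dir)
    return(invisible(bundle))
  }
  bundle
}

#' @rdname generate_dataset
#' @details `generate_null_dataset()` forces every group to share the
#'   first group's occurrence profile and drops planted enrichments, so
#'   any between-group signal found downstream is a false positive.
#' @export
generate_null_dataset <- function(config, dir = NULL) {
  generate_dataset(null_config(config), dir = dir)
}

aux_products <- c("ABC transporter permease", "MFS transporter",
                  "TonB-dependent receptor",
                  "LacI family transcriptional regulator",
                  "sugar porin", "two-component sensor histidine kinase")
neutral_products <- c("DNA polymerase III subunit alpha",
                      "50S ribosomal protein L3", "elongation factor Tu",
                      "chaperonin GroEL", "DUF1501 domain-containing protein",
                      "serine/threonine protein kinase",
                      "aminotransferase class I protein")

# Gene-level tables for one genome. `present` is the genome's true family
# set; planted clusters and isolated background CAZymes are laid out on
# `n_contigs` contigs.
simulate_genome <- function(cfg, genome_id, present) {
  n_genes <- sample_from(seq(cfg$genes_per_genome[1L],
                             cfg$genes_per_genome[2L]))
  contig_sizes <- rep(n_genes %/% cfg$n_contigs, cfg$n_contigs)
  contig_sizes[1L] <- contig_sizes[1L] + n_genes %% cfg$n_contigs
  contig_ids <- sprintf("%s_c%d", genome_id, seq_len(cfg$n_contigs))

  role <- lapply(contig_sizes, function(sz) rep("OTHER", sz))
  locked <- lapply(contig_sizes, function(sz) rep(FALSE, sz))
  fam_at <- lapply(contig_sizes, function(sz) rep(NA_character_, sz))

  # ---- planted clusters ----
  planted <- list()
  n_cluster_caz_total <- 0L
  for (k in seq_len(cfg$cgc_per_genome)) {
    ci <- ((k - 1L) %% cfg$n_contigs) + 1L
    sz <- contig_sizes[ci]
    n_caz <- sample_from(seq(cfg$cgc_cazymes[1L], cfg$cgc_cazymes[2L]))
    n_aux <- sample_from(seq(cfg$cgc_auxiliary[1L], cfg$cgc_auxiliary[2L]))
    sig_roles <- sample(c(rep("CAZYME", n_caz), rep("AUXILIARY", n_aux)))
    gaps <- sample_from(0:cfg$max_gap, length(sig_roles) - 1L,
                        replace = TRUE)
    span_len <- length(sig_roles) + sum(gaps)
    n_on_contig <- length(seq(k, cfg$cgc_per_genome, by = cfg$n_contigs))
    slot <- (k - 1L) %/% cfg$n_contigs + 1L
    seg <- floor(sz / n_on_contig)
    lo <- (slot - 1L) * seg + cfg$flank_gap + 1L
    hi <- slot * seg - cfg$flank_gap - span_len
    if (hi < lo) stop("planted cluster does not fit contig segment")
    start <- sample_from(seq(lo, hi))
    pos <- start
    sig_pos <- integer(length(sig_roles))
    for (s in seq_along(sig_roles)) {
      sig_pos[s] <- pos
      role[[ci]][pos] <- sig_roles[s]
      if (s < length(sig_roles)) pos <- pos + gaps[s] + 1L
    }
    lock_lo <- max(1L, start - cfg$flank_gap)
    lock_hi <- min(sz, sig_pos[length(sig_pos)] + cfg$flank_gap)
    locked[[ci]][lock_lo:lock_hi] <- TRUE
    planted[[k]] <- data.frame(genome_id = genome_id,
                               contig_id = contig_ids[ci],
                               first_rank = start - 1L,
                               last_rank = sig_pos[length(sig_pos)] - 1L,
                               n_cazymes = n_caz, n_auxiliary = n_aux,
                               stringsAsFactors = FALSE)
    caz_pos <- sig_pos[sig_roles == "CAZYME"]
    fam_at[[ci]][caz_pos] <- if (length(present)) {
      sample_from(present, length(caz_pos), replace = TRUE)
    } else {
      rep("GH13_10", length(caz_pos))  # degenerate family-free genome
    }
    n_cluster_caz_total <- n_cluster_caz_total + n_caz
  }
  # ---- background classified CAZymes: one isolated gene per family ----
  # draw from the currently valid (unlocked) positions so packing is
  # limited only by true capacity, not by rejection luck
  used <- unique(unlist(lapply(fam_at, function(f) f[!is.na(f)])))
  for (f in setdiff(present, used)) {
    candidates <- do.call(rbind, lapply(seq_len(cfg$n_contigs), function(ci) {
      open <- which(!locked[[ci]])
      if (length(open)) cbind(ci, open) else NULL
    }))
    if (is.null(candidates) || nrow(candidates) == 0L) {
      stop("could not place isolated CAZyme gene: genome too dense for ",
           "the family set (increase genes_per_genome or lower occurrence)")
    }
    pick <- candidates[sample.int(nrow(candidates), 1L), ]
    ci <- pick[1L]; p <- pick[2L]
    role[[ci]][p] <- "CAZYME"
    fam_at[[ci]][p] <- f
    lo <- max(1L, p - cfg$max_gap - 1L)
    hi <- min(contig_sizes[ci], p + cfg$max_gap + 1L)
    locked[[ci]][lo:hi] <- TRUE
  }
  # ---- per-contig vectorized gene tables ----
  cbm_universe <- cfg$family_universe$label[
    cfg$family_universe$cazy_class == "CBM"]
  gene_tabs <- list()
  ov_rows <- list()
  offset <- 0L
  for (ci in seq_len(cfg$n_contigs)) {
    sz <- contig_sizes[ci]
    lens <- 3L * sample(100:700, sz, replace = TRUE)
    gaps <- sample(20:200, sz, replace = TRUE)
    starts <- cumsum(c(1L, lens[-sz] + gaps[-sz]))
    ends <- starts + lens - 1L
    gids <- sprintf("%s_g%05d", genome_id, offset + seq_len(sz))
    product <- sample_from(neutral_products, sz, replace = TRUE)
    product[stats::runif(sz) < 0.3] <- "hypothetical protein"
    r <- role[[ci]]
    aux_pos <- which(r == "AUXILIARY")
    product[aux_pos] <- sample_from(aux_products, length(aux_pos),
                                    replace = TRUE)
    caz_pos <- which(r == "CAZYME")
    for (p in caz_pos) {
      fam <- fam_at[[ci]][p]
      hmmer <- fam
      if (stats::runif(1) < cfg$frac_multimodular) {
        n_extra <- sample(1:2, 1L, prob = c(0.8, 0.2))
        hmmer <- c(hmmer, sample_from(cbm_universe, n_extra,
                                      replace = TRUE))
      }
      hotpep <- if (stats::runif(1) < 0.7) family_label(hmmer[1L]) else
        character(0)
      diamond <- if (stats::runif(1) < 0.8) family_label(hmmer) else
        character(0)
      product[p] <- sprintf("%s family protein", family_label(fam))
      ov_rows[[length(ov_rows) + 1L]] <- list(gid = gids[p], hmmer = hmmer,
                                              hotpep = hotpep,
                                              diamond = diamond)
    }
    gene_tabs[[ci]] <- data.frame(
      genome_id = genome_id, contig_id = contig_ids[ci], gene_id = gids,
      start = starts, end = ends,
      strand = sample_from(c("+", "-"), sz, replace = TRUE),
      rank = seq_len(sz) - 1L, product = product,
      aa_length = lens %/% 3L - 1L, stringsAsFactors = FALSE)
    offset <- offset + sz
  }
  gene_tab <- do.call(rbind, c(gene_tabs, list(make.row.names = FALSE)))
  status_vec <- ifelse(unlist(role) == "CAZYME", "classified", "none")
  # ---- unclassified CAZymes (DIAMOND-only) and GT-only genes ----
  n_classified <- sum(status_vec == "classified")
  n_unc <- round(n_classified * cfg$frac_unclassified /
                 (1 - cfg$frac_unclassified))
  free <- which(status_vec == "none")
  if (n_unc > 0L && length(free) >= n_unc) {
    unc_idx <- sample_from(free, n_unc)
    status_vec[unc_idx] <- "unclassified"
    free <- setdiff(free, unc_idx)
    fam_pool <- family_label(cfg$family_universe$label[
      cfg$family_universe$cazy_class %in% c("GH", "PL", "CE")])
    for (i in unc_idx) {
      ov_rows[[length(ov_rows) + 1L]] <- list(
        gid = gene_tab$gene_id[i], hmmer = character(0),
        hotpep = character(0), diamond = sample_from(fam_pool))
    }
  }
  if (cfg$n_gt_genes > 0L && length(free) >= cfg$n_gt_genes) {
    gt_idx <- sample_from(free, cfg$n_gt_genes)
    for (i in gt_idx) {
      ov_rows[[length(ov_rows) + 1L]] <- list(
        gid = gene_tab$gene_id[i],
        hmmer = sprintf("GT%d", sample_from(c(2L, 4L, 51L))),
        hotpep = character(0), diamond = character(0))
    }
  }
  ov <- data.frame(gene_id = vapply(ov_rows, `[[`, character(1), "gid"),
                   stringsAsFactors = FALSE)
  ov$hmmer <- lapply(ov_rows, `[[`, "hmmer")
  ov$hotpep <- lapply(ov_rows, `[[`, "hotpep")
  ov$diamond <- lapply(ov_rows, `[[`, "diamond")
  ov <- ov[order(ov$gene_id), , drop = FALSE]
  rownames(ov) <- NULL
  list(genes = gene_tab, overview = ov,
       truth = data.frame(gene_id = gene_tab$gene_id, status = status_vec,
                          stringsAsFactors = FALSE),
       planted = do.call(rbind, c(planted, list(make.row.names = FALSE))))
}

# signal peptides, alignments and metadata for all genomes + ground truth
assemble_bundle <- function(cfg, genomes, genome_ids, genome_group) {
  sp_types_pos <- c("SP", "TAT", "LIPO")
  sp_rows <- list(); o6_rows <- list(); meta_rows <- list()
  truth_ident <- list()
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    calls <- call_consensus(g$overview)
    subs <- assign_substrates(calls, cfg$substrate_map)
    cat_of <- tapply(subs$substrate_category, subs$gene_id,
                     function(x) x[1L])
    n <- nrow(g$genes)
    cat_vec <- rep("background", n)
    hit <- match(g$genes$gene_id, names(cat_of))
    cat_vec[!is.na(hit)] <- unlist(cat_of)[hit[!is.na(hit)]]
    p_pos <- unname(cfg$sp_prob[cat_vec])
    has_sp <- stats::runif(n) < p_pos
    sp_type <- rep("NONE", n)
    sp_type[has_sp] <- sample_from(sp_types_pos, sum(has_sp),
                                   replace = TRUE)
    sp_p <- round(ifelse(has_sp, stats::runif(n, 0.7, 1),
                         stats::runif(n, 0.5, 1)), 4)
    sp_rows[[i]] <- data.frame(gene_id = g$genes$gene_id, sp_type = sp_type,
                               probability = sp_p, stringsAsFactors = FALSE)
    # alignment hits for classified genes
    cls_ids <- calls$gene_id[calls$status == "classified"]
    if (length(cls_ids)) {
      best_ident <- round(pmin(95, pmax(18, stats::rnorm(length(cls_ids),
                                                         52, 13))), 1)
      n_hits <- sample_from(1:3, length(cls_ids), replace = TRUE)
      for (k in seq_along(cls_ids)) {
        idents <- c(best_ident[k],
                    if (n_hits[k] > 1L)
                      round(stats::runif(n_hits[k] - 1L, 15,
                                         best_ident[k]), 1))
        bits <- seq(300, by = -40, length.out = n_hits[k])
        o6_rows[[length(o6_rows) + 1L]] <- data.frame(
          qseqid = cls_ids[k],
          sseqid = sprintf("CAZyDB|%s|%03d", cls_ids[k], seq_len(n_hits[k])),
          pident = idents, length = 200L, mismatch = 10L, gapopen = 1L,
          qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
          evalue = 1e-50, bitscore = bits, stringsAsFactors = FALSE)
      }
      truth_ident[[i]] <- data.frame(gene_id = cls_ids,
                                     best_identity = best_ident,
                                     stringsAsFactors = FALSE)
    }
    meta_rows[[i]] <- data.frame(
      genome_id = genome_ids[i], class = genome_group[i],
      order = paste0(genome_group[i], "_order"),
      family = paste0(genome_group[i], "_family"),
      habitat = sample_from(cfg$habitats),
      completeness = round(stats::runif(1, cfg$completeness[1L],
                                        cfg$completeness[2L]), 2),
      contamination = round(stats::runif(1, cfg$contamination[1L],
                                         cfg$contamination[2L]), 2),
      genome_size_bp = max(g$genes$end),
      n_proteins = nrow(g$genes), stringsAsFactors = FALSE)
  }
  ground_truth <- list(
    planted_cgcs = do.call(rbind, c(lapply(genomes, `[[`, "planted"),
                                    list(make.row.names = FALSE))),
    gene_status = do.call(rbind, c(lapply(genomes, `[[`, "truth"),
                                   list(make.row.names = FALSE))),
    signal_peptides = do.call(rbind, c(sp_rows,
                                       list(make.row.names = FALSE))),
    best_identities = do.call(rbind, c(truth_ident,
                                       list(make.row.names = FALSE))),
    enriched_families = cfg$planted_enrichments$family,
    groups = stats::setNames(genome_group, genome_ids))
  list(genes = lapply(genomes, `[[`, "genes"),
       overview = lapply(genomes, `[[`, "overview"),
       signalp = ground_truth$signal_peptides,
       outfmt6 = do.call(rbind, c(o6_rows, list(make.row.names = FALSE))),
       metadata = do.call(rbind, c(meta_rows, list(make.row.names = FALSE))),
       substrate_map = cfg$substrate_map,
       ground_truth = ground_truth)
}

write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "gff"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "dbcan"), showWarnings = FALSE)
  for (gid in names(bundle$genes)) {
    write_gff(bundle$genes[[gid]], file.path(dir, "gff",
                                             paste0(gid, ".gff")))
    write_dbcan_overview(bundle$overview[[gid]],
                         file.path(dir, "dbcan", paste0(gid, ".tsv")))
  }
  write_tsv(bundle$signalp, file.path(dir, "signalp.tsv"))
  utils::write.table(bundle$outfmt6, file.path(dir, "outfmt6.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_tsv(bundle$metadata, file.path(dir, "metadata.tsv"))
  write_tsv(bundle$substrate_map, file.path(dir, "substrate_map.tsv"))
  gt <- bundle$ground_truth
  gt$groups <- as.list(gt$groups)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Write gene and overview tables in their external formats
#'
#' `write_gff()` emits prodigal-flavoured GFF3 (CDS features with `ID`,
#' `product` and `aa_length` attributes); `write_dbcan_overview()` emits
#' the 5-column dbCAN2 overview dialect with `-` for no hit and `+`
#' joining multiple families. Both round-trip through [read_gff()] /
#' [read_dbcan_overview()].
#'
#' @param genes,overview tables in the internal layouts.
#' @param path output file.
#' @export
write_gff <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    writeLines(sprintf(
      "%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s;aa_length=%d",
      genes$contig_id, genes$start, genes$end, genes$strand, genes$gene_id,
      genes$product, genes$aa_length), con)
  }
  invisible(path)
}

#' @rdname write_gff
#' @export
write_dbcan_overview <- function(overview, path) {
  fmt <- function(x) {
    vapply(x, function(v) if (length(v)) paste(v, collapse = "+") else "-",
           character(1))
  }
  n_tools <- (lengths(overview$hmmer) > 0) + (lengths(overview$hotpep) > 0) +
    (lengths(overview$diamond) > 0)
  tab <- data.frame(GeneID = overview$gene_id, HMMER = fmt(overview$hmmer),
                    Hotpep = fmt(overview$hotpep),
                    DIAMOND = fmt(overview$diamond),
                    check.names = FALSE, stringsAsFactors = FALSE)
  tab[["#ofTools"]] <- n_tools
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Paper-flavoured simulation preset
#'
#' Two groups of 30 genomes contrasting a GH-diverse taxon (roughly 40
#' distinct GH families per genome) with a GH-poor one (roughly 8),
#' echoing the contrast between carbohydrate-degrading specialists and
#' anammox-type genomes at toy scale, with two planted clusters per
#' genome.
#'
#' @param seed RNG seed.
#' @param n_per_group genomes per group.
#' @return [sim_config()] object.
#' @export
paper_flavoured_config <- function(seed = 1L, n_per_group = 30L) {
  sim_config(
    seed = seed,
    groups = stats::setNames(c(n_per_group, n_per_group),
                             c("gh_diverse", "gh_poor")),
    class_probs = list(
      gh_diverse = c(GH = 0.68, PL = 0.45, CE = 0.5, AA = 0.2, CBM = 0.45),
      gh_poor = c(GH = 0.14, PL = 0.1, CE = 0.25, AA = 0.08, CBM = 0.12)))
}
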
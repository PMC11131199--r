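#' CAZyme family diversity of a genome
#'
#' Number of distinct families (or subfamily-distinct labels) of one
#' CAZyme class encoded by a genome. At `"family"` granularity subfamily
#' suffixes collapse (`GH5_2` and `GH5_46` both count as `GH5`); at
#' `"subfamily"` granularity every distinct label counts. GT modules never
#' appear here (they are excluded at consensus time).
#'
#' @param calls consensus calls for one genome.
#' @param cazy_class one of GH, PL, CE, AA, CBM.
#' @param granularity `"family"` or `"subfamily"`.
#' @return non-negative integer.
#' @export
family_diversity <- function(calls, cazy_class,
                             granularity = c("family", "subfamily")) {
  granularity <- match.arg(granularity)
  labels <- unlist(calls$modules[calls$status == "classified"],
                   use.names = FALSE)
  labels <- labels[cazy_class_of(labels) == cazy_class]
  if (granularity == "family") labels <- family_label(labels)
  length(unique(labels))
}

#' Quality filtering of genomes
#'
#' Keeps genomes satisfying all of: completeness strictly above
#' `min_completeness` (%), contamination strictly below
#' `max_contamination` (%), and at least `min_cazymes` classified CAZyme
#' genes. Boundary genomes (completeness exactly 75, contamination exactly
#' 10) are excluded. The exclusion log names the first failed criterion
#' per genome. Idempotent: filtering a filtered set changes nothing.
#'
#' @param metadata metadata table ([read_metadata()]).
#' @param calls_by_genome named list of consensus call tables, one per
#'   genome; every genome with calls must have metadata (hard error
#'   otherwise).
#' @param min_completeness,max_contamination,min_cazymes thresholds
#'   (defaults 75, 10, 10).
#' @return list with `retained` (character vector of genome ids) and
#'   `log` (data.frame `genome_id`, `retained`, `reason`).
#' @export
quality_filter <- function(metadata, calls_by_genome,
                           min_completeness = 75, max_contamination = 10,
                           min_cazymes = 10) {
  missing_meta <- setdiff(names(calls_by_genome), metadata$genome_id)
  if (length(missing_meta)) {
    stop("genome(s) with calls but no metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  n_caz <- vapply(metadata$genome_id, function(g) {
    calls <- calls_by_genome[[g]]
    if (is.null(calls)) 0L else sum(calls$status == "classified")
  }, integer(1))
  reason <- rep(NA_character_, nrow(metadata))
  reason[metadata$completeness <= min_completeness] <-
    sprintf("completeness <= %g", min_completeness)
  fail_cont <- is.na(reason) & metadata$contamination >= max_contamination
  reason[fail_cont] <- sprintf("contamination >= %g", max_contamination)
  fail_caz <- is.na(reason) & n_caz < min_cazymes
  reason[fail_caz] <- sprintf("fewer than %d CAZymes", min_cazymes)
  list(retained = metadata$genome_id[is.na(reason)],
       log = data.frame(genome_id = metadata$genome_id,
                        retained = is.na(reason),
                        reason = ifelse(is.na(reason), "", reason),
                        stringsAsFactors = FALSE))
}

#' Group small taxonomic classes as "other class"
#'
#' Classes represented by fewer than `min_n` genomes are relabelled
#' `"other class"`; genome counts are conserved.
#'
#' @param metadata metadata table (post quality filter).
#' @param min_n minimum class size (default 10).
#' @return metadata with relabelled `class` column.
#' @export
group_small_classes <- function(metadata, min_n = 10) {
  sizes <- table(metadata$class)
  small <- names(sizes)[sizes < min_n]
  metadata$class[metadata$class %in% small] <- "other class"
  metadata
}

#' Rare CAZyme families
#'
#' Families present in strictly fewer than `threshold` (fraction) of the
#' genomes in a presence matrix.
#'
#' @param profile binary genomes x families matrix ([profile_matrix()]).
#' @param threshold occupancy fraction (default 0.05).
#' @return character vector of family labels.
#' @export
rare_families <- function(profile, threshold = 0.05) {
  if (nrow(profile) == 0L || ncol(profile) == 0L) {
    stop("empty profile matrix")
  }
  occ <- colMeans(profile > 0)
  colnames(profile)[occ < threshold]
}

#' Multi-modularity summary of a genome
#'
#' A multi-modular CAZyme carries two or more modules (catalytic and/or
#' CBM) on one polypeptide. A "combination" is the order-insensitive
#' multiset of module labels of one gene (so GH5+CBM6 and CBM6+GH5 are the
#' same combination, and GH10+CBM2+CBM2 keeps the duplicated CBM2).
#'
#' @param calls consensus calls for one genome.
#' @return list with `n_multimodular`, `module_count_distribution` (table
#'   over module counts of classified genes) and `unique_combinations`
#'   (number of distinct multi-module combinations).
#' @export
multimodularity <- function(calls) {
  cls <- calls[calls$status == "classified", , drop = FALSE]
  counts <- lengths(cls$modules)
  combos <- vapply(cls$modules, function(m) paste(sort(m), collapse = "+"),
                   character(1))
  multi <- counts >= 2L
  list(n_multimodular = sum(multi),
       module_count_distribution = table(counts),
       unique_combinations = length(unique(combos[multi])))
}

#' Spearman correlation between GH and CBM family diversity
#'
#' Rank correlation (average ranks for ties) between per-genome GH family
#' diversity and CBM family diversity within one taxon group. The p-value
#' uses the t approximation for `n >= 10` and exhaustive permutation of
#' one margin for `n < 10` — small taxon groups deserve honest
#' small-sample p-values. Zero variance in either vector leaves rho
#' undefined (`NA`).
#'
#' @param gh,cbm numeric vectors of equal length (per-genome diversities).
#' @return list `rho`, `p`, `n`, `method`.
#' @export
gh_cbm_correlation <- function(gh, cbm) {
  stopifnot(length(gh) == length(cbm))
  n <- length(gh)
  if (n < 3L) stop("need at least 3 genomes")
  if (stats::sd(gh) == 0 || stats::sd(cbm) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(gh); ry <- rank(cbm)
  rho <- stats::cor(rx, ry)
  if (n >= 10L) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  } else {
    perms <- permutations_of(n, rx)   # rows: permuted rx rank vectors
    mx <- mean(rx); sx <- stats::sd(rx)
    my <- mean(ry); sy <- stats::sd(ry)
    rho_all <- (perms %*% ry - n * mx * my) / ((n - 1) * sx * sy)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

# all n! permutations of a rank vector as rows (n <= 9)
permutations_of <- function(n, v = NULL) {
  if (n > 9L) stop("exhaustive permutations limited to n <= 9")
  base <- if (is.null(v)) seq_len(n) else v
  perm_idx <- function(k) {
    if (k == 1L) return(matrix(1L, 1, 1))
    sub <- perm_idx(k - 1L)
    do.call(rbind, lapply(seq_len(k), function(i) {
      rest <- setdiff(seq_len(k), i)
      cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
    }))
  }
  idx <- perm_idx(n)
  matrix(base[idx], nrow(idx), n)
}

#' Per-genome CAZyome summary
#'
#' One row of the per-genome summary table: family and subfamily diversity
#' per class, gene counts, CAZyme coding frequency (percentage of
#' protein-coding genes that are classified CAZymes), GH+CBM coding
#' frequency, the T1/T2 trend split (T1 when GH+CBM frequency exceeds
#' `trend_threshold` percent; exactly at the threshold is T2),
#' multi-modularity and the unclassified ratio. `n_proteins` comes from
#' metadata (the gene caller's count); a mismatch with the gene table is
#' tolerated with a warning.
#'
#' @param genome_id genome identifier.
#' @param calls consensus calls for the genome.
#' @param n_proteins protein-coding gene count from metadata.
#' @param trend_threshold percent threshold separating trends (default 2).
#' @param n_genes_seen optional number of genes in the gene table, used
#'   only to warn on disagreement with `n_proteins`.
#' @return one-row data.frame.
#' @export
genome_summary <- function(genome_id, calls, n_proteins,
                           trend_threshold = 2, n_genes_seen = NULL) {
  stopifnot(n_proteins > 0)
  if (!is.null(n_genes_seen) && n_genes_seen != n_proteins) {
    warning(genome_id, ": metadata n_proteins (", n_proteins,
            ") differs from gene table (", n_genes_seen, ")")
  }
  n_caz <- sum(calls$status == "classified")
  has_ghcbm <- vapply(calls$modules, function(m) {
    any(cazy_class_of(m) %in% c("GH", "CBM"))
  }, logical(1))
  coding_freq <- 100 * n_caz / n_proteins
  ghcbm_freq <- 100 * sum(has_ghcbm & calls$status == "classified") /
    n_proteins
  mm <- multimodularity(calls)
  out <- data.frame(genome_id = genome_id, n_cazyme_genes = n_caz,
                    coding_frequency = coding_freq,
                    gh_cbm_frequency = ghcbm_freq,
                    trend = if (ghcbm_freq > trend_threshold) "T1" else "T2",
                    n_multimodular = mm$n_multimodular,
                    n_unique_module_combinations = mm$unique_combinations,
                    unclassified_ratio = unclassified_ratio(calls),
                    stringsAsFactors = FALSE)
  for (cl in c("GH", "PL", "CE", "AA", "CBM")) {
    out[[paste0("div_", cl, "_family")]] <-
      family_diversity(calls, cl, "family")
    out[[paste0("div_", cl, "_subfamily")]] <-
      family_diversity(calls, cl, "subfamily")
  }
  out
}

#' Per-taxon aggregate of genome summaries
#'
#' Mean and standard deviation of every numeric summary column within each
#' taxon group, in the usual "47 +/- 19" reporting style.
#'
#' @param summaries row-bound [genome_summary()] table.
#' @param groups character vector of group labels, one per row.
#' @return data.frame with one row per group and `<metric>_mean` /
#'   `<metric>_sd` columns plus `n_genomes`.
#' @export
taxon_aggregate <- function(summaries, groups) {
  stopifnot(nrow(summaries) == length(groups))
  num <- summaries[vapply(summaries, is.numeric, logical(1))]
  res <- lapply(split(seq_along(groups), groups), function(i) {
    row <- data.frame(group = groups[i[1L]], n_genomes = length(i),
                      stringsAsFactors = FALSE)
    for (nm in names(num)) {
      row[[paste0(nm, "_mean")]] <- mean(num[[nm]][i], na.rm = TRUE)
      row[[paste0(nm, "_sd")]] <- stats::sd(num[[nm]][i], na.rm = TRUE)
    }
    row
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
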
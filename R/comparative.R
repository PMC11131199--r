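#' Build a genomes x families profile matrix
#'
#' Collects the module labels of all classified genes per genome into a
#' matrix with genomes as rows and family labels as columns, either as
#' presence/absence or as module counts. Granularity `"family"` collapses
#' subfamily suffixes; `"subfamily"` keeps every distinct label.
#'
#' @param calls_by_genome named list of consensus call tables.
#' @param values `"presence"` (0/1) or `"count"`.
#' @param granularity `"family"` or `"subfamily"`.
#' @param cazy_classes classes to include (default all non-GT).
#' @return numeric matrix with genome ids as rownames, sorted labels as
#'   colnames.
#' @export
profile_matrix <- function(calls_by_genome, values = c("presence", "count"),
                           granularity = c("family", "subfamily"),
                           cazy_classes = c("GH", "PL", "CE", "AA", "CBM")) {
  values <- match.arg(values)
  granularity <- match.arg(granularity)
  per_genome <- lapply(calls_by_genome, function(calls) {
    labels <- unlist(calls$modules[calls$status == "classified"],
                     use.names = FALSE)
    labels <- labels[cazy_class_of(labels) %in% cazy_classes]
    if (granularity == "family") labels <- family_label(labels)
    table(labels)
  })
  all_labels <- sort(unique(unlist(lapply(per_genome, names))))
  mat <- matrix(0, nrow = length(per_genome), ncol = length(all_labels),
                dimnames = list(names(calls_by_genome), all_labels))
  for (i in seq_along(per_genome)) {
    t <- per_genome[[i]]
    mat[i, names(t)] <- as.numeric(t)
  }
  if (values == "presence") mat <- (mat > 0) + 0
  mat
}

#' Jaccard distance matrix of binary CAZyme profiles
#'
#' `d(i, j) = 1 - |A  intersect B| / |A union B|` over the family sets of
#' two genomes. Values above zero in the input count as presence. A pair
#' of genomes that both encode no family at all has an undefined Jaccard
#' distance; it is emitted as 0 with a warning (such genomes cannot
#' survive the quality filter).
#'
#' @param profile genomes x families matrix.
#' @return a symmetric `dist`-convertible matrix with zero diagonal.
#' @export
jaccard_matrix <- function(profile) {
  bin <- (profile > 0) + 0
  d <- as.matrix(suppressWarnings(
    vegan::vegdist(bin, method = "jaccard", binary = TRUE)))
  if (any(is.nan(d))) {
    warning("genome pair(s) with empty family sets: distance set to 0")
    d[is.nan(d)] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(profile), rownames(profile))
  d
}

#' Principal coordinate analysis (classical MDS)
#'
#' Gower double-centering of the squared distance matrix followed by
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of the positive eigenvalues (via [stats::cmdscale()]). Negative
#' eigenvalues — the signature of non-Euclidean distances like Jaccard —
#' are reported, never silently dropped.
#'
#' @param d square symmetric distance matrix with zero diagonal
#'   (asymmetric input is a hard error).
#' @param n_axes number of coordinate axes to return (default
#'   `nrow(d) - 1`).
#' @return list with `coordinates` (genomes x axes), `eigenvalues`
#'   (descending, including negatives) and `proportion_explained`
#'   (relative to the sum of positive eigenvalues).
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(d)
  if (is.null(n_axes)) n_axes <- n - 1L
  # cmdscale warns when the requested k exceeds the configuration's rank;
  # the dropped axes have zero/negative eigenvalues, which we report anyway
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d),
                                          k = min(n_axes, n - 1L),
                                          eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  coords <- fit$points
  if (is.null(dim(coords)) || ncol(coords) == 0L) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(d), "Axis1"))
  } else {
    colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  }
  pos <- eig[eig > 0]
  prop <- if (length(pos)) eig / sum(pos) else rep(0, length(eig))
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = prop)
}

check_groups <- function(d, groups) {
  stopifnot(nrow(as.matrix(d)) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) {
    stop("group(s) of size 1: ", paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  invisible(sizes)
}

#' Permutational multivariate ANOVA on a distance matrix
#'
#' PERMANOVA pseudo-F from the within/between sum-of-squares decomposition
#' of the distance matrix, with a label-permutation p-value
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)` (via
#' [vegan::adonis2()]). Permutations are seeded for reproducibility.
#'
#' @param d distance matrix.
#' @param groups group label per genome; at least two groups of size
#'   >= 2 (a singleton group is a hard error).
#' @param n_permutations number of label permutations (default 999).
#' @param seed RNG seed for the permutation schedule.
#' @return list `statistic` (pseudo-F), `p`, `n_permutations`,
#'   `r_squared`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1L) {
  check_groups(d, groups)
  df <- data.frame(groups = factor(groups))
  dd <- stats::as.dist(as.matrix(d))
  res <- withr::with_seed(seed,
    vegan::adonis2(dd ~ groups, data = df, permutations = n_permutations))
  list(statistic = res$F[1L], p = res$`Pr(>F)`[1L],
       n_permutations = n_permutations, r_squared = res$R2[1L])
}

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean rank of between-group distances - mean rank of within-group
#' distances) / (M / 2)` with `M = n(n-1)/2` pairwise distances ranked
#' with average ties; `R` lies in `[-1, 1]`, positive when genomes are
#' more similar within groups than between. Permutation p-value as in
#' [permanova()] (via [vegan::anosim()]).
#'
#' @inheritParams permanova
#' @return list `statistic` (R), `p`, `n_permutations`.
#' @export
anosim <- function(d, groups, n_permutations = 999, seed = 1L) {
  check_groups(d, groups)
  dd <- stats::as.dist(as.matrix(d))
  res <- withr::with_seed(seed,
    vegan::anosim(dd, grouping = factor(groups),
                  permutations = n_permutations))
  list(statistic = unname(res$statistic), p = res$signif,
       n_permutations = n_permutations)
}

#' Per-family Kruskal-Wallis enrichment with BH correction
#'
#' Tests every family column of a profile matrix for differential
#' presence/abundance across groups with the tie-corrected Kruskal-Wallis
#' statistic, adjusts the p-values over all tested families with the
#' Benjamini-Hochberg step-up procedure, and flags families with adjusted
#' `p < alpha`. Families constant across all genomes cannot be tested and
#' are recorded with `tested = FALSE`.
#'
#' @param profile genomes x families matrix (presence or counts).
#' @param groups group label per genome.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame, one row per family: per-group means, `kw_statistic`,
#'   `p`, `p_adjusted`, `tested`, `significant`, `enriched_group` (group
#'   with highest mean among tested families).
#' @export
kw_enrichment <- function(profile, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  fams <- colnames(profile)
  res <- data.frame(family_label = fams, stringsAsFactors = FALSE)
  for (g in levels(groups)) {
    res[[paste0("mean_", g)]] <- colMeans(profile[groups == g, , drop = FALSE])
  }
  res$kw_statistic <- NA_real_
  res$p <- NA_real_
  res$tested <- FALSE
  for (j in seq_along(fams)) {
    x <- profile[, j]
    if (length(unique(x)) < 2L) next  # constant: untestable
    kw <- stats::kruskal.test(x, groups)
    res$kw_statistic[j] <- unname(kw$statistic)
    res$p[j] <- kw$p.value
    res$tested[j] <- TRUE
  }
  res$p_adjusted <- NA_real_
  res$p_adjusted[res$tested] <- stats::p.adjust(res$p[res$tested],
                                                method = "BH")
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  group_means <- as.matrix(res[paste0("mean_", levels(groups))])
  res$enriched_group <- levels(groups)[max.col(group_means,
                                               ties.method = "first")]
  res$enriched_group[!res$tested] <- NA_character_
  res
}

#' LEfSe-style linear discriminant effect size
#'
#' For families passing the Kruskal-Wallis screen, an effect size in the
#' style of LEfSe: each genome's profile row is normalised to relative
#' abundance and scaled to one million, a one-axis linear discriminant is
#' fitted on the screened features over bootstrap subsamples (2/3 of each
#' group, 30 rounds), and the per-family effect size is the average of the
#' raw between-class mean difference and its discriminant-weighted
#' counterpart, averaged over bootstraps. The reported score is
#' `log10(effect size)` (floored at 0) and families with score above
#' `lda_threshold` are flagged. When the within-class scatter is singular
#' the round falls back to the raw mean-difference effect size and the
#' family is marked `lda_fallback`. Scores are rank-comparable with
#' LEfSe's, not bit-identical (its exact bootstrap schedule is not
#' public).
#'
#' @param profile genomes x families matrix.
#' @param groups group label per genome (2 groups supported).
#' @param kw_alpha screen level on BH-adjusted Kruskal-Wallis p.
#' @param lda_threshold log10 effect size cut-off for flagging
#'   (default 4).
#' @param n_boot,subsample bootstrap rounds and per-group subsampling
#'   fraction.
#' @param seed RNG seed for the bootstrap schedule.
#' @return the [kw_enrichment()] table with added `lda_score`,
#'   `lda_flagged`, `lda_fallback` columns (scores only for screened
#'   families).
#' @export
lda_effect_size <- function(profile, groups, kw_alpha = 0.05,
                            lda_threshold = 4, n_boot = 30,
                            subsample = 2 / 3, seed = 1L) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("LDA effect size supports exactly 2 groups")
  enr <- kw_enrichment(profile, groups, alpha = kw_alpha)
  keep <- which(!is.na(enr$p_adjusted) & enr$p_adjusted < kw_alpha)
  enr$lda_score <- NA_real_
  enr$lda_flagged <- FALSE
  enr$lda_fallback <- FALSE
  if (length(keep) == 0L) return(enr)
  # LEfSe convention: per-sample relative abundance scaled to 1e6
  totals <- rowSums(profile)
  totals[totals == 0] <- 1
  scaled <- profile / totals * 1e6
  feat <- scaled[, keep, drop = FALSE]
  g1 <- which(groups == levels(groups)[1L])
  g2 <- which(groups == levels(groups)[2L])
  eff <- matrix(NA_real_, n_boot, length(keep))
  fallback <- rep(FALSE, length(keep))
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      i1 <- sample(g1, max(2L, floor(length(g1) * subsample)))
      i2 <- sample(g2, max(2L, floor(length(g2) * subsample)))
      sub <- rbind(feat[i1, , drop = FALSE], feat[i2, , drop = FALSE])
      cls <- factor(rep(levels(groups), c(length(i1), length(i2))))
      raw_diff <- abs(colMeans(feat[i1, , drop = FALSE]) -
                      colMeans(feat[i2, , drop = FALSE]))
      w <- tryCatch({
        # drop features constant in the subsample; MASS::lda rejects them
        ok <- apply(sub, 2, function(x) stats::sd(x) > 0)
        if (!any(ok)) stop("all features constant")
        # collinear screened features are routine for presence profiles;
        # lda still returns a usable first axis
        fit <- suppressWarnings(MASS::lda(sub[, ok, drop = FALSE],
                                          grouping = cls))
        wfull <- numeric(ncol(sub))
        wfull[ok] <- fit$scaling[, 1L]
        wfull / sqrt(sum(wfull^2))
      }, error = function(e) NULL)
      if (is.null(w)) {
        eff[b, ] <- raw_diff
        fallback <- fallback | TRUE
      } else {
        proj_diff <- abs(sum(w * (colMeans(sub[cls == levels(cls)[1L], ,
                                               drop = FALSE]) -
                                  colMeans(sub[cls == levels(cls)[2L], ,
                                               drop = FALSE]))))
        eff[b, ] <- (raw_diff + abs(w) * proj_diff) / 2
      }
    }
  })
  mean_eff <- colMeans(eff)
  enr$lda_score[keep] <- log10(pmax(mean_eff, 1))
  enr$lda_flagged[keep] <- enr$lda_score[keep] > lda_threshold
  enr$lda_fallback[keep] <- fallback
  enr
}
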
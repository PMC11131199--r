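#' Default family-to-substrate map
#'
#' A small, documented lookup covering GH/PL families with well
#' characterised main activities: fucosidases and agarases targeting algal
#' polysaccharides, cellulases/xylanases targeting the lignocellulose
#' backbone, amylases on glucans, beta-glycosidases on oligosaccharides,
#' peptidoglycan/chitin (NAG-based) enzymes and pectin lyases. Real
#' analyses should supply a comprehensive map via [read_substrate_map()];
#' this default exists so the pipeline and its tests are self-contained.
#'
#' @return data.frame `family_label`, `biomass_category`,
#'   `substrate_category`.
#' @export
default_substrate_map <- function() {
  entry <- function(fams, bio, sub) {
    data.frame(family_label = fams, biomass_category = bio,
               substrate_category = sub, stringsAsFactors = FALSE)
  }
  map <- rbind(
    entry(c("GH29", "GH95", "GH107", "GH139", "GH141", "GH151", "GH168",
            "GH118", "GH16", "PL6", "PL7", "PL17"),
          "algal", "algal polysaccharides"),
    entry(c("GH5", "GH9", "GH10", "GH11", "GH62", "GH6", "GH8", "GH44",
            "GH45", "GH48", "GH51", "GH54", "GH67", "GH115"),
          "plant", "lignocellulose"),
    entry(c("GH13", "GH15", "GH57", "GH77", "GH4"), "plant", "glucans"),
    entry(c("GH1", "GH2", "GH3", "GH31", "GH35", "GH42", "GH43"),
          "plant", "oligosaccharides"),
    entry(c("GH102", "GH103", "GH18", "GH19", "GH20", "GH23", "GH73"),
          "other", "NAG-based"),
    entry(c("PL1", "PL9", "PL11", "GH28", "GH78", "GH105"),
          "plant", "pectin"),
    entry(c("GH109", "GH33", "PL8"), "other", "other"))
  validate_substrate_map(map)
}

#' Annotate GH/PL modules with biomass and substrate categories
#'
#' Walks the classified consensus calls and annotates every GH and PL
#' module (other classes are ignored) with its biomass and substrate
#' category. Lookup is subfamily-first: a `GH5_2` module uses a `GH5_2`
#' map entry when present, otherwise falls back to `GH5`. Modules whose
#' family is absent from the map get category `"unassigned"`.
#'
#' @param calls consensus calls ([call_consensus()]).
#' @param map substrate map ([read_substrate_map()] /
#'   [default_substrate_map()]).
#' @return data.frame with one row per GH/PL module: `gene_id`, `label`,
#'   `cazy_class`, `biomass_category`, `substrate_category`.
#' @export
assign_substrates <- function(calls, map = default_substrate_map()) {
  map <- validate_substrate_map(map)
  cls <- calls[calls$status == "classified", , drop = FALSE]
  gene_id <- rep(cls$gene_id, lengths(cls$modules))
  label <- unlist(cls$modules, use.names = FALSE)
  if (length(label) == 0L) {
    return(data.frame(gene_id = character(0), label = character(0),
                      cazy_class = character(0),
                      biomass_category = character(0),
                      substrate_category = character(0),
                      stringsAsFactors = FALSE))
  }
  klass <- cazy_class_of(label)
  keep <- klass %in% c("GH", "PL")
  gene_id <- gene_id[keep]; label <- label[keep]; klass <- klass[keep]
  i_sub <- match(label, map$family_label)
  i_fam <- match(family_label(label), map$family_label)
  idx <- ifelse(is.na(i_sub), i_fam, i_sub)
  data.frame(
    gene_id = gene_id, label = label, cazy_class = klass,
    biomass_category = ifelse(is.na(idx), "unassigned",
                              map$biomass_category[idx]),
    substrate_category = ifelse(is.na(idx), "unassigned",
                                map$substrate_category[idx]),
    stringsAsFactors = FALSE)
}

#' Target-specificity (assigned) ratio of a genome
#'
#' Fraction of a genome's GH/PL modules with an assigned substrate
#' function: mapped modules over all GH/PL modules. The unit is the module
#' (a bifunctional GH5+GH10 protein contributes two), matching the module
#' splitting applied at consensus time. A genome without GH/PL modules
#' yields `NA`.
#'
#' @param substrates module annotation table from [assign_substrates()]
#'   for one genome.
#' @return a number in `[0, 1]` or `NA`.
#' @export
assigned_ratio <- function(substrates) {
  n_all <- nrow(substrates)
  if (n_all == 0L) return(NA_real_)
  sum(substrates$substrate_category != "unassigned") / n_all
}

#' Per-category substrate counts for one genome
#'
#' @param substrates [assign_substrates()] output for one genome.
#' @return named integer vector over the substrate vocabulary (plus
#'   `unassigned`), counting GH/PL modules.
#' @export
substrate_counts <- function(substrates) {
  lv <- c(substrate_categories, "unassigned")
  table(factor(substrates$substrate_category, levels = lv))
}

#' Secretion ratio of a substrate category
#'
#' Among the genes of one genome carrying at least one GH/PL module mapped
#' to `category`, the fraction predicted to carry a signal peptide of one
#' of the requested types. Signal peptides belong to whole proteins, so
#' the unit here is the gene; a gene whose modules span several categories
#' counts once in each. With the default `sp_types` any predicted type
#' except `NONE` counts as "secreted".
#'
#' @param substrates [assign_substrates()] output for one genome.
#' @param sp_calls signal peptide table ([read_signalp()]).
#' @param category a substrate category, or `"any"` for all mapped GH/PL
#'   genes.
#' @param sp_types character subset of SP/LIPO/TAT/TATLIPO/PILIN counted
#'   as positive.
#' @return a number in `[0, 1]`, or `NA` when no gene falls in the
#'   category. Genes missing from `sp_calls` count as no signal peptide.
#' @export
secretion_ratio <- function(substrates, sp_calls, category = "any",
                            sp_types = c("SP", "LIPO", "TAT", "TATLIPO",
                                         "PILIN")) {
  stopifnot(!"NONE" %in% sp_types)
  if (identical(category, "any")) {
    genes <- unique(substrates$gene_id[
      substrates$substrate_category != "unassigned"])
  } else {
    genes <- unique(substrates$gene_id[
      substrates$substrate_category == category])
  }
  if (length(genes) == 0L) return(NA_real_)
  sp <- sp_calls$sp_type[match(genes, sp_calls$gene_id)]
  sp[is.na(sp)] <- "NONE"
  mean(sp %in% sp_types)
}

#' Per-genome substrate profile
#'
#' Bundles [substrate_counts()], [assigned_ratio()] and per-category
#' [secretion_ratio()] into the one-row summary emitted by the pipeline.
#'
#' @param genome_id genome identifier.
#' @inheritParams secretion_ratio
#' @return one-row data.frame: `genome_id`, one `n_<category>` column per
#'   substrate category, `assigned_ratio`, `secretion_ratio_any` and one
#'   `secretion_<category>` column per category.
#' @export
substrate_profile <- function(genome_id, substrates, sp_calls) {
  cnt <- substrate_counts(substrates)
  out <- data.frame(genome_id = genome_id, stringsAsFactors = FALSE)
  for (cat in names(cnt)) {
    out[[paste0("n_", gsub("[ /-]", "_", cat))]] <- as.integer(cnt[[cat]])
  }
  out$assigned_ratio <- assigned_ratio(substrates)
  out$secretion_ratio_any <- secretion_ratio(substrates, sp_calls, "any")
  for (cat in substrate_categories) {
    out[[paste0("secretion_", gsub("[ /-]", "_", cat))]] <-
      secretion_ratio(substrates, sp_calls, cat)
  }
  out
}
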
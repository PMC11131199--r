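#' Read prodigal-style gene calls from a GFF3 file
#'
#' Parses the CDS features of a GFF3 file into a gene table, one row per
#' protein-coding gene. Gene order along each contig ("rank", 0-based) is
#' assigned by ascending start coordinate, ties broken by ascending end and
#' then gene id; all downstream neighbourhood logic (CGC detection) operates
#' on ranks only, so the 1-based inclusive GFF coordinate convention never
#' leaks into clustering.
#'
#' @param path path to a GFF3 file whose CDS features carry an `ID`
#'   attribute (prodigal dialect).
#' @param genome_id genome identifier stored with every gene; defaults to
#'   the file name without extension.
#' @return data.frame with columns `genome_id`, `contig_id`, `gene_id`,
#'   `start`, `end`, `strand`, `rank`, `product`, `aa_length`.
#' @details A CDS with `end < start` or a duplicated `ID` is a hard error
#'   naming the offending line/id. An empty file yields an empty table with
#'   a warning. `aa_length` is derived as `(end - start + 1) / 3 - 1`
#'   (floored, at least 1) unless an `aa_length` attribute is present.
#' @export
read_gff <- function(path, genome_id = NULL) {
  stopifnot(file.exists(path))
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    warning("no CDS features in ", path)
    return(empty_gene_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad)) {
    stop("malformed GFF3 line (fewer than 9 columns): line ", bad[1L])
  }
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- c("seqid", "source", "type", "start", "end", "score",
                  "strand", "phase", "attributes")
  tab <- tab[tab$type == "CDS", , drop = FALSE]
  if (nrow(tab) == 0L) {
    warning("no CDS features in ", path)
    return(empty_gene_table())
  }
  start <- as.integer(tab$start)
  end <- as.integer(tab$end)
  if (anyNA(start) || anyNA(end)) {
    stop("non-integer CDS coordinates in ", path)
  }
  if (any(end < start)) {
    i <- which(end < start)[1L]
    stop("CDS with end < start (", tab$seqid[i], ":", start[i], "-", end[i],
         ") in ", path)
  }
  ids <- gff_attribute(tab$attributes, "ID")
  if (anyNA(ids)) stop("CDS feature without ID attribute in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in ", path, ": ",
         ids[duplicated(ids)][1L])
  }
  product <- gff_attribute(tab$attributes, "product")
  product[is.na(product)] <- ""
  aa_attr <- suppressWarnings(as.integer(gff_attribute(tab$attributes,
                                                       "aa_length")))
  aa_len <- ifelse(!is.na(aa_attr), aa_attr,
                   pmax(1L, (end - start + 1L) %/% 3L - 1L))
  genes <- data.frame(genome_id = genome_id, contig_id = tab$seqid,
                      gene_id = ids, start = start, end = end,
                      strand = tab$strand, rank = NA_integer_,
                      product = product, aa_length = aa_len,
                      stringsAsFactors = FALSE)
  assign_ranks(genes)
}

empty_gene_table <- function() {
  data.frame(genome_id = character(0), contig_id = character(0),
             gene_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), rank = integer(0),
             product = character(0), aa_length = integer(0),
             stringsAsFactors = FALSE)
}

gff_attribute <- function(attrs, key) {
  re <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attrs, regexec(re, attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
         character(1))
}

# deterministic per-contig 0-based rank by (start, end, gene_id)
assign_ranks <- function(genes) {
  ord <- order(genes$contig_id, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- stats::ave(genes$start, genes$contig_id,
                           FUN = seq_along) - 1L
  rownames(genes) <- NULL
  genes
}

#' Read a dbCAN2-style "overview" annotation table
#'
#' The overview table reports, per gene, the family labels assigned by each
#' of the three dbCAN2 tools. Expected layout is the fixed 5-column dbCAN2
#' dialect: `GeneID`, `HMMER`, `Hotpep`, `DIAMOND`, `#ofTools`, tab
#' separated, with `-` for "no hit" and `+` joining multiple families. The
#' `#ofTools` column is ignored (recomputed downstream from the parsed
#' lists). Other layouts are rejected, not guessed.
#'
#' @param path path to the overview TSV.
#' @param on_bad_label `"fail"` (default) stops on a label that does not
#'   parse under the CAZy grammar; `"skip"` drops the offending gene row
#'   with a warning naming its gene id.
#' @return data.frame with one row per gene and list-columns `hmmer`,
#'   `hotpep`, `diamond` holding character vectors of family labels.
#' @export
read_dbcan_overview <- function(path, on_bad_label = c("fail", "skip")) {
  on_bad_label <- match.arg(on_bad_label)
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  expected <- c("GeneID", "HMMER", "Hotpep", "DIAMOND", "#ofTools")
  if (!identical(names(tab), expected)) {
    stop("not a dbCAN2 overview table; expected columns ",
         paste(expected, collapse = ", "))
  }
  hmmer <- lapply(tab$HMMER, split_label_field)
  hotpep <- lapply(tab$Hotpep, split_label_field)
  diamond <- lapply(tab$DIAMOND, split_label_field)
  all_ok <- mapply(function(h, p, d) all(is_cazy_label(c(h, p, d))),
                   hmmer, hotpep, diamond)
  if (any(!all_ok)) {
    bad_ids <- tab$GeneID[!all_ok]
    if (on_bad_label == "fail") {
      stop("unparsable CAZyme label for gene(s): ",
           paste(bad_ids, collapse = ", "))
    }
    warning("skipping gene(s) with unparsable CAZyme label: ",
            paste(bad_ids, collapse = ", "))
    keep <- all_ok
    tab <- tab[keep, , drop = FALSE]
    hmmer <- hmmer[keep]; hotpep <- hotpep[keep]; diamond <- diamond[keep]
  }
  out <- data.frame(gene_id = tab$GeneID, stringsAsFactors = FALSE)
  out$hmmer <- hmmer
  out$hotpep <- hotpep
  out$diamond <- diamond
  out
}

#' Read signalP6-style signal peptide predictions
#'
#' @param path TSV with columns `gene_id`, `sp_type`, `probability`.
#'   `sp_type` must be one of SP, LIPO, TAT, TATLIPO, PILIN, NONE and the
#'   probability must lie in `[0, 1]`; violations are hard errors.
#' @return data.frame `gene_id`, `sp_type`, `probability`.
#' @export
read_signalp <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need_columns(tab, c("gene_id", "sp_type", "probability"), path)
  ok_types <- c("SP", "LIPO", "TAT", "TATLIPO", "PILIN", "NONE")
  if (!all(tab$sp_type %in% ok_types)) {
    stop("unknown signal peptide type: ",
         paste(setdiff(tab$sp_type, ok_types), collapse = ", "))
  }
  if (any(tab$probability < 0 | tab$probability > 1)) {
    stop("signal peptide probability outside [0,1] in ", path)
  }
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene_id in signal peptide table ", path)
  }
  tab[c("gene_id", "sp_type", "probability")]
}

#' Read a genome metadata table
#'
#' @param path TSV with header columns `genome_id`, `class`, `order`,
#'   `family`, `habitat`, `completeness`, `contamination`,
#'   `genome_size_bp`, `n_proteins`. Completeness is a percentage in
#'   `[0, 100]` (a value above 100 is a hard error), contamination a
#'   percentage `>= 0`.
#' @return validated data.frame with those columns.
#' @export
read_metadata <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- c("genome_id", "class", "order", "family", "habitat",
            "completeness", "contamination", "genome_size_bp", "n_proteins")
  need_columns(tab, cols, path)
  if (anyDuplicated(tab$genome_id)) {
    stop("duplicate genome_id in metadata ", path)
  }
  if (any(tab$completeness > 100 | tab$completeness < 0)) {
    stop("completeness outside [0,100] in ", path)
  }
  if (any(tab$contamination < 0)) stop("negative contamination in ", path)
  if (any(tab$n_proteins <= 0)) stop("non-positive n_proteins in ", path)
  tab[cols]
}

#' Read tabular alignment best-hit input (BLAST/DIAMOND outfmt6)
#'
#' Consumes the standard 12-column outfmt6 layout; only `qseqid`, `sseqid`,
#' `pident` and `bitscore` are retained. Percent identity outside
#' `[0, 100]` is a hard error.
#'
#' @param path path to a headerless outfmt6 TSV.
#' @return data.frame `qseqid`, `sseqid`, `pident`, `bitscore`.
#' @export
read_outfmt6 <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 12L) {
    stop("expected 12 outfmt6 columns, found ", ncol(tab), " in ", path)
  }
  out <- data.frame(qseqid = as.character(tab[[1]]),
                    sseqid = as.character(tab[[2]]),
                    pident = as.numeric(tab[[3]]),
                    bitscore = as.numeric(tab[[12]]),
                    stringsAsFactors = FALSE)
  if (any(out$pident < 0 | out$pident > 100)) {
    stop("percent identity outside [0,100] in ", path)
  }
  out
}

#' Read a family-to-substrate mapping table
#'
#' @param path TSV with columns `family_label`, `biomass_category`,
#'   `substrate_category`. Biomass categories come from the closed
#'   vocabulary \{algal, plant, algal/plant, other\} and substrate
#'   categories from \{algal polysaccharides, glucans, oligosaccharides,
#'   lignocellulose, NAG-based, pectin, other\}. A duplicated
#'   `family_label` is a hard error.
#' @return validated data.frame.
#' @seealso [default_substrate_map()] for the small map shipped with the
#'   package.
#' @export
read_substrate_map <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need_columns(tab, c("family_label", "biomass_category",
                      "substrate_category"), path)
  validate_substrate_map(tab)
}

validate_substrate_map <- function(tab) {
  if (anyDuplicated(tab$family_label)) {
    stop("duplicate family_label in substrate map: ",
         tab$family_label[duplicated(tab$family_label)][1L])
  }
  if (!all(is_cazy_label(tab$family_label))) {
    stop("invalid family label in substrate map")
  }
  if (!all(tab$biomass_category %in% biomass_categories)) {
    stop("unknown biomass category: ",
         paste(setdiff(tab$biomass_category, biomass_categories),
               collapse = ", "))
  }
  if (!all(tab$substrate_category %in% substrate_categories)) {
    stop("unknown substrate category: ",
         paste(setdiff(tab$substrate_category, substrate_categories),
               collapse = ", "))
  }
  tab[c("family_label", "biomass_category", "substrate_category")]
}

#' @rdname read_substrate_map
#' @format NULL
#' @export
biomass_categories <- c("algal", "plant", "algal/plant", "other")

#' @rdname read_substrate_map
#' @format NULL
#' @export
substrate_categories <- c("algal polysaccharides", "glucans",
                          "oligosaccharides", "lignocellulose", "NAG-based",
                          "pectin", "other")

need_columns <- function(tab, cols, path) {
  missing <- setdiff(cols, names(tab))
  if (length(missing)) {
    stop("missing column(s) ", paste(missing, collapse = ", "), " in ", path)
  }
  invisible(tab)
}

#' Write pipeline tables as TSV
#'
#' Plain `write.table` wrapper with the conventions used for every pipeline
#' output (tab separator, no quoting, no row names); list-columns of labels
#' are collapsed with `";"`.
#'
#' @param tab data.frame to write.
#' @param path output path.
#' @export
write_tsv <- function(tab, path) {
  is_list <- vapply(tab, is.list, logical(1))
  for (j in which(is_list)) {
    tab[[j]] <- vapply(tab[[j]], paste, character(1), collapse = ";")
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
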
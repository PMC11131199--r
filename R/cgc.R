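#' Assign clustering roles to genes
#'
#' For CGC detection each gene on a contig plays one of three roles:
#' \describe{
#'   \item{CAZYME}{a classified CAZyme (consensus status `classified`);}
#'   \item{AUXILIARY}{a non-CAZyme gene whose product annotation matches a
#'     transcription-factor or transporter signature (the gene classes
#'     that, together with CAZymes, make up polysaccharide utilisation
#'     loci);}
#'   \item{OTHER}{everything else, including unclassified CAZymes (they
#'     carry no family assignment, so they cannot anchor a cluster, but
#'     they are reported inside the cluster "unassigned" fraction).}
#' }
#' CAZyme status always wins: a classified CAZyme whose product text
#' happens to mention a regulator stays CAZYME.
#'
#' @param genes gene table for one genome ([read_gff()] layout).
#' @param calls consensus calls from [call_consensus()].
#' @param signature_config character vector of case-insensitive regular
#'   expressions defining auxiliary products; see
#'   [default_auxiliary_signatures()]. An empty vector is allowed (with a
#'   warning): clusters then require two CAZymes.
#' @param hypothetical_patterns case-insensitive patterns marking a product
#'   as hypothetical.
#' @return the gene table with added columns `role`, `is_hypothetical`,
#'   `is_unclassified_cazyme`, plus `modules` carried over from `calls`.
#' @export
assign_auxiliary <- function(genes, calls,
                             signature_config = default_auxiliary_signatures(),
                             hypothetical_patterns = "hypothetical protein") {
  if (length(signature_config) == 0L) {
    warning("empty auxiliary signature list: clusters will require >= 2 CAZymes")
  }
  status <- calls$status[match(genes$gene_id, calls$gene_id)]
  status[is.na(status)] <- "none"   # genes absent from the overview
  modules <- calls$modules[match(genes$gene_id, calls$gene_id)]
  modules[vapply(modules, is.null, logical(1))] <- list(character(0))
  is_aux <- rep(FALSE, nrow(genes))
  for (pat in signature_config) {
    is_aux <- is_aux | grepl(pat, genes$product, ignore.case = TRUE)
  }
  role <- ifelse(status == "classified", "CAZYME",
                 ifelse(is_aux, "AUXILIARY", "OTHER"))
  is_hyp <- rep(FALSE, nrow(genes))
  for (pat in hypothetical_patterns) {
    is_hyp <- is_hyp | grepl(pat, genes$product, ignore.case = TRUE)
  }
  genes$role <- role
  genes$is_hypothetical <- is_hyp
  genes$is_unclassified_cazyme <- status == "unclassified"
  genes$modules <- modules
  genes
}

#' @rdname assign_auxiliary
#' @export
default_auxiliary_signatures <- function() {
  c("transcription(al)? regulator", "transcription factor", "transporter",
    "permease", "porin", "TonB", "\\bMFS\\b", "\\bABC\\b",
    "sigma factor", "two-component")
}

#' Detect CAZyme gene clusters (CGCs) on one contig
#'
#' Implements the co-localisation rule used for planctomycetotal genomes:
#' a CGC consists of at least one CAZyme-coding gene together with at least
#' one auxiliary gene (transcription factor or transporter) or another
#' CAZyme, with consecutive signature genes separated by at most
#' `max_gap` other genes. Detection is greedy chaining over the contig's
#' gene order: signature genes (CAZYME or AUXILIARY) are scanned by rank,
#' two consecutive signature genes join the same chain iff at most
#' `max_gap` non-signature genes lie between them, and a maximal chain is
#' emitted as a CGC iff it satisfies the composition rule
#' (>=1 CAZyme and (>=1 auxiliary or >=2 CAZymes)). Emitted clusters
#' start and end on a signature gene; clusters on one contig never
#' overlap. Strand plays no part; contig ends terminate chains.
#'
#' @param genes role-annotated gene table for \emph{one} contig
#'   ([assign_auxiliary()] output), sorted by rank (unsorted input is an
#'   error).
#' @param max_gap maximum number of intervening non-signature genes between
#'   consecutive signature members (default 2); negative values are an
#'   error.
#' @return data.frame with one row per CGC: `cgc_id`, `genome_id`,
#'   `contig_id`, `first_rank`, `last_rank`, `n_cazymes`, `n_auxiliary`,
#'   `n_other`, and list-columns `member_ranks`, `signature_ranks`,
#'   `member_gene_ids`.
#' @export
detect_cgcs <- function(genes, max_gap = 2L) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  stopifnot(all(c("rank", "role") %in% names(genes)))
  if (length(unique(genes$contig_id)) > 1L) {
    stop("detect_cgcs() expects genes of a single contig; see detect_cgcs_genome()")
  }
  if (is.unsorted(genes$rank, strictly = TRUE)) {
    stop("genes must be sorted by rank")
  }
  sig <- which(genes$role %in% c("CAZYME", "AUXILIARY"))
  out <- list()
  if (length(sig) > 0L) {
    # chain breaks where the inter-signature gap exceeds max_gap
    gaps <- diff(genes$rank[sig]) - 1L
    chain_id <- cumsum(c(1L, as.integer(gaps > max_gap)))
    for (ch in split(sig, chain_id)) {
      roles <- genes$role[ch]
      n_caz <- sum(roles == "CAZYME")
      n_aux <- sum(roles == "AUXILIARY")
      if (n_caz >= 1L && (n_aux >= 1L || n_caz >= 2L)) {
        span <- which(genes$rank >= genes$rank[ch[1L]] &
                      genes$rank <= genes$rank[ch[length(ch)]])
        out[[length(out) + 1L]] <- list(
          first_rank = genes$rank[ch[1L]],
          last_rank = genes$rank[ch[length(ch)]],
          n_cazymes = n_caz, n_auxiliary = n_aux,
          n_other = length(span) - n_caz - n_aux,
          member_ranks = genes$rank[span],
          signature_ranks = genes$rank[ch],
          member_gene_ids = genes$gene_id[span])
      }
    }
  }
  if (length(out) == 0L) return(empty_cgc_table())
  res <- data.frame(
    cgc_id = sprintf("%s_cgc%02d", genes$contig_id[1L], seq_along(out)),
    genome_id = genes$genome_id[1L], contig_id = genes$contig_id[1L],
    first_rank = vapply(out, `[[`, numeric(1), "first_rank"),
    last_rank = vapply(out, `[[`, numeric(1), "last_rank"),
    n_cazymes = vapply(out, `[[`, numeric(1), "n_cazymes"),
    n_auxiliary = vapply(out, `[[`, numeric(1), "n_auxiliary"),
    n_other = vapply(out, `[[`, numeric(1), "n_other"),
    stringsAsFactors = FALSE)
  res$member_ranks <- lapply(out, `[[`, "member_ranks")
  res$signature_ranks <- lapply(out, `[[`, "signature_ranks")
  res$member_gene_ids <- lapply(out, `[[`, "member_gene_ids")
  res
}

empty_cgc_table <- function() {
  res <- data.frame(cgc_id = character(0), genome_id = character(0),
                    contig_id = character(0), first_rank = numeric(0),
                    last_rank = numeric(0), n_cazymes = numeric(0),
                    n_auxiliary = numeric(0), n_other = numeric(0),
                    stringsAsFactors = FALSE)
  res$member_ranks <- list()
  res$signature_ranks <- list()
  res$member_gene_ids <- list()
  res
}

#' @rdname detect_cgcs
#' @export
detect_cgcs_genome <- function(genes, max_gap = 2L) {
  pieces <- lapply(split(genes, genes$contig_id), function(g) {
    detect_cgcs(g[order(g$rank), , drop = FALSE], max_gap = max_gap)
  })
  if (length(pieces) == 0L) return(empty_cgc_table())
  do.call(rbind, c(pieces, list(make.row.names = FALSE)))
}

#' Per-genome CGC co-localisation fractions
#'
#' Summarises how much of a genome's CAZyme repertoire is co-localised:
#' \describe{
#'   \item{frac_cazymes_in_cgc}{classified CAZyme genes inside any CGC span
#'     over all classified CAZyme genes;}
#'   \item{frac_gh_in_cgc}{same restricted to genes carrying at least one
#'     GH module;}
#'   \item{frac_hypothetical_in_cgc}{hypothetical-product genes among all
#'     genes inside CGC spans;}
#'   \item{frac_unassigned_in_cgc}{genes inside CGC spans that are neither
#'     CAZymes nor auxiliary (regulatory/transport) genes, over all genes
#'     inside CGC spans.}
#' }
#' Fractions with an empty denominator (e.g. a genome without CAZymes, or
#' without any CGC for the within-cluster fractions) are `NA`.
#'
#' @param genes role-annotated gene table for one genome.
#' @param cgcs CGC table from [detect_cgcs_genome()].
#' @return one-row data.frame of the four fractions plus `n_cgcs`.
#' @export
cgc_fractions <- function(genes, cgcs) {
  in_span <- rep(FALSE, nrow(genes))
  if (nrow(cgcs) > 0L) {
    for (i in seq_len(nrow(cgcs))) {
      in_span <- in_span | (genes$contig_id == cgcs$contig_id[i] &
                            genes$rank >= cgcs$first_rank[i] &
                            genes$rank <= cgcs$last_rank[i])
    }
  }
  is_caz <- genes$role == "CAZYME"
  has_gh <- vapply(genes$modules, function(m) any(cazy_class_of(m) == "GH"),
                   logical(1))
  frac <- function(num, den) if (den == 0L) NA_real_ else num / den
  data.frame(
    genome_id = if (nrow(genes)) genes$genome_id[1L] else NA_character_,
    n_cgcs = nrow(cgcs),
    frac_cazymes_in_cgc = frac(sum(is_caz & in_span), sum(is_caz)),
    frac_gh_in_cgc = frac(sum(has_gh & in_span), sum(has_gh)),
    frac_hypothetical_in_cgc = frac(sum(genes$is_hypothetical & in_span),
                                    sum(in_span)),
    frac_unassigned_in_cgc = frac(sum(in_span & !is_caz &
                                      genes$role != "AUXILIARY"),
                                  sum(in_span)),
    stringsAsFactors = FALSE)
}

#' Write CGC tables
#'
#' Writes the CGC TSV plus a BED-like companion (contig, 0-based half-open
#' rank span, cgc_id) for genome-browser style inspection.
#'
#' @param cgcs CGC table.
#' @param tsv_path,bed_path output paths (either may be `NULL` to skip).
#' @export
write_cgcs <- function(cgcs, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    tab <- cgcs[setdiff(names(cgcs), c("member_ranks", "signature_ranks"))]
    write_tsv(tab, tsv_path)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(contig = cgcs$contig_id, start = cgcs$first_rank,
                      end = cgcs$last_rank + 1, name = cgcs$cgc_id)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}
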
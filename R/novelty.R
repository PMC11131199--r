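#' Best-hit novelty records from alignment tables
#'
#' Reduces an outfmt6 hit table to one best hit per query: maximal
#' bitscore, ties broken by higher percent identity and then lexicographic
#' subject id — a deterministic, order-independent choice. Queries listed
#' in `query_ids` but absent from the hit table get a record with missing
#' identity. The identity of the best hit against a reference CAZyme set
#' is the novelty proxy: hits below `low_identity` percent flag putatively
#' novel enzymes.
#'
#' @param hits data.frame from [read_outfmt6()].
#' @param query_ids optional character vector of genes that should appear
#'   in the output even without hits (typically all classified CAZymes).
#' @param low_identity percent identity below which a gene is flagged
#'   (default 30).
#' @return data.frame `gene_id`, `best_hit_subject`, `best_identity`,
#'   `low_identity_flag` (FALSE when there is no hit).
#' @export
best_hits <- function(hits, query_ids = NULL, low_identity = 30) {
  ord <- order(hits$qseqid, -hits$bitscore, -hits$pident, hits$sseqid)
  h <- hits[ord, , drop = FALSE]
  best <- h[!duplicated(h$qseqid), , drop = FALSE]
  out <- data.frame(gene_id = best$qseqid,
                    best_hit_subject = best$sseqid,
                    best_identity = best$pident,
                    stringsAsFactors = FALSE)
  if (!is.null(query_ids)) {
    missing <- setdiff(query_ids, out$gene_id)
    if (length(missing)) {
      out <- rbind(out, data.frame(gene_id = missing,
                                   best_hit_subject = NA_character_,
                                   best_identity = NA_real_,
                                   stringsAsFactors = FALSE))
    }
    out <- out[match(sort(query_ids), out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out$low_identity_flag <- !is.na(out$best_identity) &
    out$best_identity < low_identity
  out
}

#' Summarise best-hit identity distributions
#'
#' Median, interquartile range and fraction of low-identity (< 30 percent
#' by default) best hits, per grouping level (family, taxon, ...). Groups
#' without any identity value are skipped. Summaries are invariant to
#' input row order.
#'
#' @param records [best_hits()] output.
#' @param grouping character vector, one label per record.
#' @param low_identity threshold for the "novel" fraction.
#' @return data.frame `group`, `n`, `median_identity`, `q1`, `q3`,
#'   `fraction_low`.
#' @export
novelty_summary <- function(records, grouping, low_identity = 30) {
  stopifnot(nrow(records) == length(grouping))
  res <- lapply(split(seq_along(grouping), grouping), function(i) {
    ident <- records$best_identity[i]
    ident <- ident[!is.na(ident)]
    if (length(ident) == 0L) return(NULL)
    q <- stats::quantile(ident, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = grouping[i[1L]], n = length(ident),
               median_identity = q[2L], q1 = q[1L], q3 = q[3L],
               fraction_low = mean(ident < low_identity),
               stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(data.frame(group = character(0), n = integer(0),
                      median_identity = numeric(0), q1 = numeric(0),
                      q3 = numeric(0), fraction_low = numeric(0)))
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
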
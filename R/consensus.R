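#' Consensus CAZyme calling from three-tool annotations
#'
#' dbCAN2 annotates every gene with up to three tools (HMMER, Hotpep,
#' DIAMOND). The consensus rule used throughout this package is:
#' \itemize{
#'   \item a gene is a \strong{classified} CAZyme iff HMMER assigned at
#'     least one family; the HMMER labels define its module list, one
#'     module per label, with repeated labels kept as repeated modules
#'     (multi-modular proteins can carry the same CBM several times);
#'   \item a gene hit only by Hotpep and/or DIAMOND is an
#'     \strong{unclassified} CAZyme — CAZyme-like but assignable to no
#'     recognised family — and carries no modules;
#'   \item with `exclude_gt = TRUE` (the default) glycosyltransferase (GT)
#'     modules are stripped from all tools before the status is decided,
#'     since GTs build rather than break glycosidic bonds. A gene whose
#'     only evidence was GT ends up with status \strong{none}. A gene whose
#'     HMMER evidence was GT-only is also `none` (HMMER saw it, so it is
#'     never "unclassified"), even if another tool suggested a non-GT
#'     family.
#' }
#'
#' @param hits data.frame as returned by [read_dbcan_overview()]
#'   (list-columns `hmmer`, `hotpep`, `diamond`).
#' @param exclude_gt drop GT modules before calling status.
#' @return data.frame with columns `gene_id`, `status` (classified /
#'   unclassified / none), list-column `modules` (character vector of
#'   labels), `n_modules` and `tools` (list-column, subset of
#'   HMMER/Hotpep/DIAMOND supporting the final call; empty for status
#'   `none`).
#' @export
call_consensus <- function(hits, exclude_gt = TRUE) {
  stopifnot(is.data.frame(hits),
            all(c("gene_id", "hmmer", "hotpep", "diamond") %in% names(hits)))
  n <- nrow(hits)
  status <- character(n)
  modules <- vector("list", n)
  tools <- vector("list", n)
  for (i in seq_len(n)) {
    h_raw <- hits$hmmer[[i]]
    p_raw <- hits$hotpep[[i]]
    d_raw <- hits$diamond[[i]]
    if (exclude_gt) {
      h <- h_raw[cazy_class_of(h_raw) != "GT"]
      p <- p_raw[cazy_class_of(p_raw) != "GT"]
      d <- d_raw[cazy_class_of(d_raw) != "GT"]
    } else {
      h <- h_raw; p <- p_raw; d <- d_raw
    }
    if (length(h) > 0L) {
      status[i] <- "classified"
      modules[[i]] <- h
      tools[[i]] <- c("HMMER", if (length(p)) "Hotpep",
                      if (length(d)) "DIAMOND")
    } else if (length(h_raw) > 0L) {
      # HMMER evidence existed but was GT-only: never "unclassified"
      status[i] <- "none"
      modules[[i]] <- character(0)
      tools[[i]] <- character(0)
    } else if (length(p) + length(d) > 0L) {
      status[i] <- "unclassified"
      modules[[i]] <- character(0)
      tools[[i]] <- c(if (length(p)) "Hotpep", if (length(d)) "DIAMOND")
    } else {
      status[i] <- "none"
      modules[[i]] <- character(0)
      tools[[i]] <- character(0)
    }
  }
  out <- data.frame(gene_id = hits$gene_id, status = status,
                    n_modules = lengths(modules),
                    stringsAsFactors = FALSE)
  out$modules <- modules
  out$tools <- tools
  out[c("gene_id", "status", "modules", "n_modules", "tools")]
}

#' Enumerate the consensus rule over all tool-presence combinations
#'
#' Documentation/testing aid: tabulates the status produced by
#' [call_consensus()] for each of the 8 HMMER/Hotpep/DIAMOND
#' presence/absence combinations, using a generic non-GT family for
#' "present".
#'
#' @param exclude_gt passed through to [call_consensus()].
#' @return data.frame with logical columns `hmmer`, `hotpep`, `diamond`
#'   and the resulting `status`.
#' @export
consensus_truth_table <- function(exclude_gt = TRUE) {
  grid <- expand.grid(hmmer = c(FALSE, TRUE), hotpep = c(FALSE, TRUE),
                      diamond = c(FALSE, TRUE))
  hits <- data.frame(gene_id = paste0("g", seq_len(nrow(grid))),
                     stringsAsFactors = FALSE)
  hits$hmmer <- lapply(grid$hmmer, function(x) if (x) "GH13" else character(0))
  hits$hotpep <- lapply(grid$hotpep, function(x) if (x) "GH13" else character(0))
  hits$diamond <- lapply(grid$diamond, function(x) if (x) "GH13" else character(0))
  calls <- call_consensus(hits, exclude_gt = exclude_gt)
  cbind(grid, status = calls$status, stringsAsFactors = FALSE)
}

#' Ratio of unclassified CAZymes in a set of consensus calls
#'
#' The fraction of CAZyme-like genes that could not be assigned to any
#' recognised family: `unclassified / (classified + unclassified)`.
#' Genomes typically sit in the 1--5\% range.
#'
#' @param calls consensus call table from [call_consensus()].
#' @return a number in `[0, 1]`, or `NA` when the genome has no CAZyme-like
#'   genes at all.
#' @export
unclassified_ratio <- function(calls) {
  n_cls <- sum(calls$status == "classified")
  n_unc <- sum(calls$status == "unclassified")
  if (n_cls + n_unc == 0L) return(NA_real_)
  n_unc / (n_cls + n_unc)
}
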
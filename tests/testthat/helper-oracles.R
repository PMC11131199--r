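# Independent oracles and fixture builders shared across tests.

# One-row three-tool hit table.
make_hits <- function(gene_id = "g1", hmmer = character(0),
                      hotpep = character(0), diamond = character(0)) {
  hits <- data.frame(gene_id = gene_id, stringsAsFactors = FALSE)
  hits$hmmer <- list(hmmer)
  hits$hotpep <- list(hotpep)
  hits$diamond <- list(diamond)
  hits
}

# Role-annotated single-contig gene table from a role vector.
# CAZYME genes get one GH module (GH13 unless given), AUXILIARY genes a
# transporter product, OTHER genes a hypothetical/neutral product.
make_contig <- function(roles, genome_id = "gt", contig_id = "c1",
                        modules = NULL, hypothetical = NULL) {
  n <- length(roles)
  if (is.null(modules)) {
    modules <- lapply(roles, function(r) {
      if (r == "CAZYME") "GH13" else character(0)
    })
  }
  if (is.null(hypothetical)) hypothetical <- rep(FALSE, n)
  product <- ifelse(roles == "AUXILIARY", "ABC transporter permease",
                    ifelse(roles == "CAZYME", "glycoside hydrolase",
                           ifelse(hypothetical, "hypothetical protein",
                                  "elongation factor Tu")))
  g <- data.frame(genome_id = genome_id, contig_id = contig_id,
                  gene_id = sprintf("%s_g%03d", contig_id, seq_len(n)),
                  start = seq_len(n) * 1000L,
                  end = seq_len(n) * 1000L + 600L,
                  strand = "+", rank = seq_len(n) - 1L,
                  product = product, aa_length = 200L,
                  stringsAsFactors = FALSE)
  g$role <- roles
  g$is_hypothetical <- hypothetical
  g$is_unclassified_cazyme <- FALSE
  g$modules <- modules
  g
}

# Brute-force CGC oracle: enumerate every window delimited by signature
# genes, keep windows whose consecutive signature gaps are all <= max_gap
# and whose composition is valid, then retain maximal windows only.
# Returns 0-based (first_rank, last_rank) pairs, sorted.
cgc_oracle <- function(roles, max_gap) {
  sig <- which(roles %in% c("CAZYME", "AUXILIARY"))
  empty <- data.frame(first_rank = integer(0), last_rank = integer(0))
  if (length(sig) == 0L) return(empty)
  gaps <- diff(sig) - 1L
  valid <- list()
  for (a in seq_along(sig)) {
    for (b in a:length(sig)) {
      if (b > a && any(gaps[a:(b - 1L)] > max_gap)) next
      r <- roles[sig[a:b]]
      n_caz <- sum(r == "CAZYME")
      if (n_caz >= 1L && (sum(r == "AUXILIARY") >= 1L || n_caz >= 2L)) {
        valid[[length(valid) + 1L]] <- c(sig[a], sig[b])
      }
    }
  }
  if (length(valid) == 0L) return(empty)
  v <- unique(do.call(rbind, valid))
  keep <- vapply(seq_len(nrow(v)), function(i) {
    !any(v[, 1] <= v[i, 1] & v[, 2] >= v[i, 2] &
         (v[, 1] < v[i, 1] | v[, 2] > v[i, 2]))
  }, logical(1))
  v <- v[keep, , drop = FALSE]
  out <- data.frame(first_rank = v[, 1] - 1L, last_rank = v[, 2] - 1L)
  out[order(out$first_rank), , drop = FALSE]
}

# Literal Benjamini-Hochberg step-up, walking sorted p-values from the
# largest down: adj_(k) = min(adj_(k+1), m/k * p_(k)), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- 1
  for (k in seq_along(o)) {
    i <- o[k]
    r <- m - k + 1L
    running <- min(running, m / r * p[i])
    adj[i] <- running
  }
  adj
}

# Detected CGC spans as a plain sorted data.frame for comparison.
span_frame <- function(cgcs) {
  out <- data.frame(first_rank = as.integer(cgcs$first_rank),
                    last_rank = as.integer(cgcs$last_rank))
  out <- out[order(out$first_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
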
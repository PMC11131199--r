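#' CAZyme family label grammar
#'
#' CAZy module labels follow `CLASS` + family integer + optional `_` +
#' subfamily integer, where `CLASS` is one of GH, GT, PL, CE, AA, CBM
#' (e.g. `"GH5_2"`, `"CBM50"`). These helpers parse, validate and reformat
#' labels; every reader that consumes dbCAN-style annotations goes through
#' them so that an unknown class prefix is rejected at the door.
#'
#' @param labels character vector of candidate labels.
#' @return `parse_cazy_label()` returns a data.frame with columns
#'   `label`, `cazy_class`, `family` (integer) and `subfamily` (integer,
#'   `NA` when the label carries no `_` part). `is_cazy_label()` returns a
#'   logical vector. `family_label()` collapses a parsed label to family
#'   granularity (drops the subfamily suffix).
#' @examples
#' parse_cazy_label(c("GH5_2", "CBM50"))
#' family_label("GH5_2")  # "GH5"
#' @export
parse_cazy_label <- function(labels) {
  labels <- as.character(labels)
  ok <- is_cazy_label(labels)
  if (any(!ok)) {
    stop("invalid CAZyme family label(s): ",
         paste(unique(labels[!ok]), collapse = ", "))
  }
  m <- regmatches(labels, regexec(cazy_label_re, labels))
  cls <- vapply(m, `[`, character(1), 2L)
  fam <- as.integer(vapply(m, `[`, character(1), 3L))
  sub <- vapply(m, `[`, character(1), 4L)
  sub <- ifelse(sub == "", NA_character_, sub("^_", "", sub))
  data.frame(label = labels, cazy_class = cls, family = fam,
             subfamily = as.integer(sub), stringsAsFactors = FALSE)
}

cazy_label_re <- "^(GH|GT|PL|CE|AA|CBM)([0-9]+)(_[0-9]+)?$"

#' @rdname parse_cazy_label
#' @export
is_cazy_label <- function(labels) {
  grepl(cazy_label_re, as.character(labels))
}

#' @rdname parse_cazy_label
#' @export
family_label <- function(labels) {
  sub("_[0-9]+$", "", as.character(labels))
}

#' @rdname parse_cazy_label
#' @export
cazy_class_of <- function(labels) {
  sub("^(GH|GT|PL|CE|AA|CBM).*$", "\\1", as.character(labels))
}

# split a '+'-joined dbCAN field into labels; "-" and "" mean no hit
split_label_field <- function(x) {
  if (is.na(x) || x == "-" || x == "") return(character(0))
  strsplit(x, "+", fixed = TRUE)[[1]]
}
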
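# Residue-level comparison of two secondary-structure assignments:
# 8-state confusion matrix, 3-state collapse and per-class agreement.
# Rows are the reference assignment, columns the query assignment.

SS8_CLASSES <- c("None", "B", "E", "G", "H", "I", "S", "T")
SS3_CLASSES <- c("unstructured", "helical", "extended")

ss_class <- function(ss) ifelse(ss == " " | ss == "" | is.na(ss), "None", ss)

#' Cross-tabulate two per-residue assignments
#'
#' Residues are keyed by (chain, res_seq, i_code); residues present in
#' both inputs contribute one cell count, residues present in only one
#' are tallied separately as unmatched.
#'
#' @param ref,query Data frames with columns `chain`, `res_seq`, `i_code`
#'   and `ss` (8-state codes, blank/'' for none), e.g. from
#'   [parse_dssp_format()] or an `ss_assignment`.
#' @return An object of class `ss_confusion`: list with `labels`, `counts`
#'   (reference rows x query columns), `unmatched_ref`, `unmatched_query`.
#' @export
compare_assignments <- function(ref, query) {
  keyify <- function(d, who) {
    ic <- if (is.null(d$i_code)) "" else ifelse(is.na(d$i_code), "", d$i_code)
    k <- paste(d$chain, d$res_seq, ic, sep = "\r")
    if (anyDuplicated(k))
      stop(sprintf("duplicate residue key in %s input: %s", who,
                   gsub("\r", "/", k[duplicated(k)][1])))
    k
  }
  kr <- keyify(ref, "reference")
  kq <- keyify(query, "query")
  common <- intersect(kr, kq)
  counts <- matrix(0L, 8, 8, dimnames = list(SS8_CLASSES, SS8_CLASSES))
  rs <- ss_class(ref$ss)[match(common, kr)]
  qs <- ss_class(query$ss)[match(common, kq)]
  bad <- unique(c(setdiff(rs, SS8_CLASSES), setdiff(qs, SS8_CLASSES)))
  if (length(bad))
    stop("unknown secondary structure class: ", paste(bad, collapse = ", "))
  if (length(common)) {
    tab <- table(factor(rs, SS8_CLASSES), factor(qs, SS8_CLASSES))
    counts <- counts + unclass(tab)
  }
  m <- list(labels = SS8_CLASSES, counts = counts,
            unmatched_ref = length(kr) - length(common),
            unmatched_query = length(kq) - length(common))
  class(m) <- "ss_confusion"
  m
}

#' @export
print.ss_confusion <- function(x, ...) {
  cat(sprintf("<ss_confusion> %d states, %d residues matched (%d/%d unmatched)\n",
              length(x$labels), sum(x$counts), x$unmatched_ref,
              x$unmatched_query))
  print(x$counts)
  invisible(x)
}

#' Collapse an 8-state confusion matrix to 3 states
#'
#' Rows and columns are merged by the simplification mapping: G, H, I to
#' "helical", E to "extended", None, B, S, T to "unstructured".  The
#' grand total is conserved.
#'
#' @param m An 8-state `ss_confusion`.
#' @return A 3-state `ss_confusion`.
#' @export
collapse_to_3state <- function(m) {
  stopifnot(inherits(m, "ss_confusion"), identical(m$labels, SS8_CLASSES))
  map <- c(None = "unstructured", B = "unstructured", E = "extended",
           G = "helical", H = "helical", I = "helical",
           S = "unstructured", T = "unstructured")
  counts <- matrix(0L, 3, 3, dimnames = list(SS3_CLASSES, SS3_CLASSES))
  for (r in seq_len(8)) for (q in seq_len(8)) {
    counts[map[m$labels[r]], map[m$labels[q]]] <-
      counts[map[m$labels[r]], map[m$labels[q]]] + m$counts[r, q]
  }
  out <- list(labels = SS3_CLASSES, counts = counts,
              unmatched_ref = m$unmatched_ref,
              unmatched_query = m$unmatched_query)
  class(out) <- "ss_confusion"
  out
}

#' Per-class agreement
#'
#' Fraction of the reference residues of class `class` assigned the same
#' class by the query: diagonal count over the reference row total,
#' reported to 3 decimals.
#'
#' @param m An `ss_confusion`.
#' @param class Class label (one of `m$labels`).
#' @return Agreement fraction in `[0, 1]` rounded to 3 decimals; `NA`
#'   with a warning when the reference row total is zero.
#' @export
per_class_agreement <- function(m, class) {
  stopifnot(inherits(m, "ss_confusion"), class %in% m$labels)
  tot <- sum(m$counts[class, ])
  if (tot == 0) {
    warning(sprintf("agreement undefined: no reference residues of class '%s'",
                    class))
    return(NA_real_)
  }
  round(m$counts[class, class] / tot, 3)
}

#' Per-class reference totals and grand total
#'
#' @param m An `ss_confusion`.
#' @return List with `per_class` (named reference row sums) and `total`.
#' @export
class_totals <- function(m) {
  stopifnot(inherits(m, "ss_confusion"))
  rs <- rowSums(m$counts)
  list(per_class = rs, total = sum(rs))
}

#' Render a confusion matrix as tab-separated text
#'
#' @param m An `ss_confusion`.
#' @return Character vector of TSV lines (row label + counts).
#' @export
format_confusion_tsv <- function(m) {
  c(paste(c("", m$labels), collapse = "\t"),
    vapply(seq_along(m$labels), function(r)
      paste(c(m$labels[r], m$counts[r, ]), collapse = "\t"), character(1)))
}
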
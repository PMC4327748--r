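# Alignment-side utilities: annotated-sequence container, FASTA/ClustalW
# input, structure-derived 3-state annotation, identity and p-distance
# matrices.
#
# An annotated sequence is a list(id, residues, ss): `residues` is the
# gapped one-letter string (gap '-'); `ss` is an optional per-position
# label string over the legend H = helical, E = extended, C = unstructured,
# with '-' on gap positions.

new_annotated_sequence <- function(id, residues, ss = NULL) {
  if (!is.null(ss) && nchar(ss) != nchar(residues))
    stop("secondary structure annotation length differs from sequence length")
  structure(list(id = id, residues = residues, ss = ss),
            class = "annotated_sequence")
}

#' @export
print.annotated_sequence <- function(x, ...) {
  cat(sprintf("<annotated_sequence> %s (%d positions%s)\n", x$id,
              nchar(x$residues),
              if (is.null(x$ss)) "" else ", annotated"))
  invisible(x)
}

normalise_gaps <- function(x) chartr(".", "-", toupper(x))

#' Read sequences from FASTA text
#'
#' Identifiers are taken from the header up to the first whitespace;
#' '.' gaps are normalised to '-'.
#'
#' @param text Character vector of lines, single string, or file path.
#' @return List of `annotated_sequence` objects.
#' @export
read_fasta <- function(text) {
  path <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text
  } else {
    tf <- tempfile(fileext = ".fasta")
    writeLines(if (length(text) == 1) strsplit(text, "\n")[[1]] else text, tf)
    tf
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot read FASTA input: ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("empty FASTA input")
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(k)
    new_annotated_sequence(ids[k],
                           normalise_gaps(unname(as.character(set[[k]])))))
}

#' Read an alignment from ClustalW text
#'
#' Block-interleaved sequences are concatenated; the conservation line is
#' ignored; alignment rectangularity is checked.
#'
#' @param text Character vector of lines, single string, or file path.
#' @return List of `annotated_sequence` objects of equal aligned length.
#' @export
read_clustal <- function(text) {
  path <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text
  } else {
    tf <- tempfile(fileext = ".aln")
    writeLines(if (length(text) == 1) strsplit(text, "\n")[[1]] else text, tf)
    tf
  }
  # pre-validate the raw text: sequence lines start with an identifier,
  # conservation lines with whitespace; per-id lengths must agree
  raw <- readLines(path, warn = FALSE)
  if (!length(raw) || !grepl("^CLUSTAL", raw[1]))
    stop("not ClustalW input: missing CLUSTAL header line")
  body <- raw[-1]
  seq_lines <- body[grepl("^\\S", body)]
  if (!length(seq_lines)) stop("empty ClustalW input")
  ids <- sub("\\s.*$", "", seq_lines)
  segs <- sub("\\s+\\d*\\s*$", "", sub("^\\S+\\s+", "", seq_lines))
  lens <- tapply(nchar(gsub("\\s", "", segs)), factor(ids, unique(ids)), sum)
  if (length(unique(as.integer(lens))) != 1)
    stop("ragged alignment: sequences have unequal aligned lengths")
  # normalise the header spacing expected by the Biostrings reader
  body <- body[cumsum(nzchar(body)) > 0]
  tf2 <- tempfile(fileext = ".aln")
  on.exit(unlink(tf2), add = TRUE)
  writeLines(c(raw[1], "", "", body), tf2)
  a <- tryCatch(
    Biostrings::unmasked(Biostrings::readAAMultipleAlignment(tf2,
                                                             format = "clustal")),
    error = function(e) stop("cannot read ClustalW input: ",
                             conditionMessage(e)))
  if (length(a) == 0) stop("empty ClustalW input")
  lapply(seq_along(a), function(k)
    new_annotated_sequence(names(a)[k],
                           normalise_gaps(unname(as.character(a[[k]])))))
}

#' Write sequences as FASTA text
#'
#' @param seqs List of `annotated_sequence` objects.
#' @param path Optional output file.
#' @param width Line-wrap width.
#' @return Character vector of FASTA lines.
#' @export
write_fasta <- function(seqs, path = NULL, width = 60) {
  out <- unlist(lapply(seqs, function(s) {
    body <- substring(s$residues, seq(1, nchar(s$residues), width),
                      pmin(seq(1, nchar(s$residues), width) + width - 1,
                           nchar(s$residues)))
    c(paste0(">", s$id), body)
  }))
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

#' Attach structure-derived 3-state labels to an aligned sequence
#'
#' The ungapped letters of `seq` must equal the one-letter sequence of the
#' residues carrying `simplified`; labels are placed on non-gap columns
#' only (legend: H helical, E extended, C unstructured; '-' on gaps).
#'
#' @param seq An `annotated_sequence` (possibly gapped).
#' @param simplified Character vector of
#'   "helical"/"extended"/"unstructured" labels, one per structure
#'   residue (see [simplify_ss()]).
#' @param structure_seq One-letter residue string of the structure, used
#'   to verify the correspondence.
#' @return The `annotated_sequence` with its `ss` field filled.
#' @export
annotate_from_structure <- function(seq, simplified, structure_seq) {
  letters_aln <- strsplit(seq$residues, "")[[1]]
  nongap <- which(letters_aln != "-")
  ungapped <- letters_aln[nongap]
  sletters <- strsplit(structure_seq, "")[[1]]
  if (length(sletters) != length(simplified))
    stop("structure sequence and labels have different lengths")
  if (length(ungapped) != length(sletters)) {
    stop(sprintf("sequence/structure mismatch: %d aligned residues vs %d structure residues",
                 length(ungapped), length(sletters)))
  }
  mism <- which(ungapped != sletters)
  if (length(mism))
    stop(sprintf("sequence/structure mismatch at position %d ('%s' vs '%s')",
                 mism[1], ungapped[mism[1]], sletters[mism[1]]))
  legend <- c(helical = "H", extended = "E", unstructured = "C")
  ss <- rep("-", length(letters_aln))
  ss[nongap] <- legend[simplified]
  seq$ss <- paste(ss, collapse = "")
  seq
}

#' Pairwise sequence distance
#'
#' Positions where either sequence has a gap are excluded (pairwise
#' deletion); `p` is the fraction of differing residues among compared
#' positions.  Methods: `"identity"` returns percent identity
#' `100 * (1 - p)`; `"p_mega"` returns `p` as a fraction; `"p_emboss"`
#' returns `100 * p`.
#'
#' @param a,b `annotated_sequence` objects of equal aligned length.
#' @param method One of "identity", "p_emboss", "p_mega".
#' @return A single distance value.
#' @export
pairwise_distance <- function(a, b, method = c("identity", "p_emboss", "p_mega")) {
  method <- match.arg(method)
  xa <- strsplit(a$residues, "")[[1]]
  xb <- strsplit(b$residues, "")[[1]]
  if (length(xa) != length(xb))
    stop(sprintf("aligned lengths differ between '%s' and '%s'", a$id, b$id))
  cmp <- xa != "-" & xb != "-"
  if (!any(cmp))
    stop(sprintf("no comparable (gap-free) sites between '%s' and '%s'",
                 a$id, b$id))
  p <- sum(xa[cmp] != xb[cmp]) / sum(cmp)
  switch(method,
         identity = 100 * (1 - p),
         p_emboss = 100 * p,
         p_mega = p)
}

#' Distance matrix over an alignment
#'
#' @param alignment List of `annotated_sequence` objects (>= 2) of equal
#'   aligned length.
#' @inheritParams pairwise_distance
#' @return An object of class `ss_distmat`: list with `ids`, symmetric
#'   `values` matrix (zero diagonal for the p methods, 100 for identity),
#'   and `method`.
#' @export
distance_matrix <- function(alignment, method = c("identity", "p_emboss", "p_mega")) {
  method <- match.arg(method)
  stopifnot(length(alignment) >= 2)
  ids <- vapply(alignment, `[[`, character(1), "id")
  n <- length(alignment)
  v <- matrix(if (method == "identity") 100 else 0, n, n,
              dimnames = list(ids, ids))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    d <- tryCatch(pairwise_distance(alignment[[a]], alignment[[b]], method),
                  error = function(e)
                    stop(sprintf("pair (%s, %s): %s", ids[a], ids[b],
                                 conditionMessage(e))))
    v[a, b] <- v[b, a] <- d
  }
  structure(list(ids = ids, values = v, method = method),
            class = "ss_distmat")
}

#' @export
print.ss_distmat <- function(x, ...) {
  cat(sprintf("<ss_distmat> %s distances, %d sequences\n", x$method,
              length(x$ids)))
  print(round(x$values, 4))
  invisible(x)
}

#' Render a distance matrix as tab-separated text
#'
#' @param dm An `ss_distmat`.
#' @return Character vector of TSV lines suitable for spreadsheet import.
#' @export
format_distmat_tsv <- function(dm) {
  c(paste(c("", dm$ids), collapse = "\t"),
    vapply(seq_along(dm$ids), function(r)
      paste(c(dm$ids[r], sprintf("%.4f", dm$values[r, ])), collapse = "\t"),
      character(1)))
}
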
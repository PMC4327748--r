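# PDB reading and writing.  The heavy lifting (fixed-column parsing,
# alternate locations, model selection) is delegated to bio3d; this layer
# converts to the residue-indexed ss_structure and captures HELIX/SHEET
# header records.

#' Parse PDB-format text
#'
#' Reads ATOM/HETATM coordinate records into an [ss_structure] and captures
#' HELIX/SHEET header records verbatim.  Only the first MODEL of a
#' multi-model file is read; alternate locations keep the blank or 'A'
#' conformer; waters are dropped; non-water HETATM residues (e.g. MSE) are
#' retained as non-standard residues.
#'
#' @param text Character vector of PDB lines, or a single string with
#'   embedded newlines.
#' @return A list with elements `structure` (an `ss_structure`) and
#'   `ss_records` (list with data frames `helices` and `strands`, each with
#'   columns chain, start_seq, start_icode, end_seq, end_icode).
#' @export
parse_pdb <- function(text) {
  if (length(text) == 1 && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  rec <- substr(text, 1, 6)
  is_coord <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_coord)) stop("no ATOM records found in PDB input")
  for (ln in which(is_coord)) {
    xyz <- suppressWarnings(as.numeric(c(substr(text[ln], 31, 38),
                                         substr(text[ln], 39, 46),
                                         substr(text[ln], 47, 54))))
    if (anyNA(xyz) || any(!is.finite(xyz)))
      stop(sprintf("malformed coordinate field on line %d", ln))
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(text, tf)
  p <- suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, verbose = FALSE))

  at <- p$atom
  keep <- !(at$resid %in% WATER_NAMES)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no non-water ATOM records found in PDB input")
  atom <- data.frame(
    type = at$type,
    serial = at$eleno,
    atom = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    res_name = at$resid,
    chain = ifelse(is.na(at$chain), " ", at$chain),
    res_seq = at$resno,
    i_code = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy),
    stringsAsFactors = FALSE)
  s <- new_ss_structure(atom)
  list(structure = s, ss_records = parse_ss_records(p))
}

parse_ss_records <- function(p) {
  rec_df <- function(r) {
    if (is.null(r) || length(r$start) == 0) {
      return(data.frame(chain = character(), start_seq = integer(),
                        start_icode = character(), end_seq = integer(),
                        end_icode = character(), stringsAsFactors = FALSE))
    }
    icode <- function(v) {
      nm <- names(v)
      if (is.null(nm)) rep("", length(v)) else ifelse(is.na(nm), "", nm)
    }
    data.frame(chain = r$chain, start_seq = as.integer(r$start),
               start_icode = icode(r$start), end_seq = as.integer(r$end),
               end_icode = icode(r$end), stringsAsFactors = FALSE)
  }
  list(helices = rec_df(p$helix), strands = rec_df(p$sheet))
}

#' Read a PDB file
#'
#' @param path Path to a PDB-format file.
#' @inherit parse_pdb return
#' @export
read_pdb <- function(path) {
  parse_pdb(readLines(path, warn = FALSE))
}

#' Write an ss_structure as PDB-format text
#'
#' Emits standard ATOM/HETATM records with \%8.3f coordinates, one TER
#' record per chain and a final END.
#'
#' @param s An `ss_structure`.
#' @param path Optional file to write to.
#' @return Character vector of PDB lines (invisibly when `path` is given).
#' @export
write_pdb <- function(s, path = NULL) {
  a <- s$atom
  if (is.null(a) || nrow(a) == 0) {
    out <- "END"
  } else {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf), add = TRUE)
    bio3d::write.pdb(
      file = tf,
      type = a$type,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      resno = a$res_seq, resid = a$res_name, eleno = a$serial,
      elety = a$atom, chain = a$chain,
      insert = ifelse(a$i_code == "", NA, a$i_code),
      o = a$occ, b = a$b, end = FALSE)
    out <- readLines(tf, warn = FALSE)
    out <- out[substr(out, 1, 3) != "TER" & substr(out, 1, 3) != "END"]
    # one TER per chain, in file order
    last_of_chain <- which(c(a$chain[-1] != a$chain[-nrow(a)], TRUE))
    res <- character(0)
    prev <- 0
    for (k in last_of_chain) {
      res <- c(res, out[(prev + 1):k], "TER")
      prev <- k
    }
    out <- c(res, "END")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
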
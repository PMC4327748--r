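# The coordinate hierarchy used by the assignment pipeline.  An
# `ss_structure` is a light residue-indexed view over an atom table:
#   atom     - one row per atom kept from the PDB file (first conformer,
#              first model, waters removed)
#   residues - one row per residue in file order, with the working
#              numbering plus the original PDB identifiers for reporting
#   break_after - logical, TRUE between residue i and i+1 when the peptide
#              bond is broken (set by detect_chain_breaks)

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

aa_one_letter <- function(res_name) {
  out <- suppressWarnings(bio3d::aa321(res_name))
  out[is.na(out)] <- "X"
  out
}

res_label <- function(chain, res_seq, i_code) {
  paste0(chain, res_seq, ifelse(is.na(i_code) | i_code == "", "", i_code))
}

new_ss_structure <- function(atom) {
  stopifnot(is.data.frame(atom))
  if (nrow(atom) == 0) {
    residues <- data.frame(chain = character(), res_seq = integer(),
                           i_code = character(), res_name = character(),
                           one_letter = character(), standard = logical(),
                           orig_res_seq = integer(), orig_i_code = character(),
                           stringsAsFactors = FALSE)
    s <- list(atom = atom, residues = residues, break_after = logical())
    class(s) <- "ss_structure"
    return(s)
  }
  key <- paste(atom$chain, atom$res_seq, atom$i_code, atom$res_name, sep = "\r")
  # residues in file order: new residue whenever the key changes
  first <- which(c(TRUE, key[-1] != key[-length(key)]))
  atom$res_idx <- cumsum(seq_len(nrow(atom)) %in% first)
  ri <- atom[first, , drop = FALSE]
  residues <- data.frame(
    chain = ri$chain,
    res_seq = ri$res_seq,
    i_code = ri$i_code,
    res_name = ri$res_name,
    one_letter = aa_one_letter(ri$res_name),
    standard = ri$res_name %in% STANDARD_AA,
    orig_res_seq = if (!is.null(ri$orig_res_seq)) ri$orig_res_seq else ri$res_seq,
    orig_i_code = if (!is.null(ri$orig_i_code)) ri$orig_i_code else ri$i_code,
    stringsAsFactors = FALSE)
  rownames(residues) <- NULL
  s <- list(atom = atom, residues = residues,
            break_after = rep(NA, max(nrow(residues) - 1, 0)))
  class(s) <- "ss_structure"
  s
}

#' @export
print.ss_structure <- function(x, ...) {
  ch <- unique(x$residues$chain)
  cat(sprintf("<ss_structure> %d residues, %d atoms, %d chain(s): %s\n",
              nrow(x$residues), nrow(x$atom), length(ch),
              paste(ch, collapse = ", ")))
  invisible(x)
}

n_residues <- function(s) nrow(s$residues)

# n x 3 coordinate matrix of one named atom per residue (NA rows if absent)
atom_matrix <- function(s, name) {
  n <- n_residues(s)
  m <- matrix(NA_real_, n, 3)
  a <- s$atom[s$atom$atom == name, , drop = FALSE]
  if (nrow(a)) {
    a <- a[!duplicated(a$res_idx), , drop = FALSE]
    m[a$res_idx, ] <- as.matrix(a[, c("x", "y", "z")])
  }
  m
}

# backbone coordinates for the whole structure
bb_coords <- function(s) {
  list(N = atom_matrix(s, "N"), CA = atom_matrix(s, "CA"),
       C = atom_matrix(s, "C"), O = atom_matrix(s, "O"),
       H = atom_matrix(s, "H"))
}

# contiguous-segment id per residue: increments at chain boundaries and at
# detected chain breaks; runs detect_chain_breaks if not yet done
segment_ids <- function(s) {
  if (anyNA(s$break_after)) s <- detect_chain_breaks(s)
  n <- n_residues(s)
  if (n == 0) return(integer())
  newseg <- c(TRUE, s$residues$chain[-1] != s$residues$chain[-n] |
                s$break_after[seq_len(n - 1)])
  cumsum(newseg)
}

#' Detect chain breaks from peptide-bond geometry
#'
#' Marks a break between consecutive residues of the same chain when the
#' C(i)-N(i+1) distance exceeds 2.5 Angstrom or either atom is missing.
#' Turns, bridges and hydrogen-bond patterns never span a break.
#'
#' @param s An `ss_structure`.
#' @return The structure with its `break_after` field filled in.
#' @export
detect_chain_breaks <- function(s) {
  n <- n_residues(s)
  if (n < 2) {
    s$break_after <- logical(max(n - 1, 0))
    return(s)
  }
  Cm <- atom_matrix(s, "C")
  Nm <- atom_matrix(s, "N")
  i <- seq_len(n - 1)
  d <- sqrt(rowSums((Cm[i, , drop = FALSE] - Nm[i + 1, , drop = FALSE])^2))
  same_chain <- s$residues$chain[i] == s$residues$chain[i + 1]
  s$break_after <- same_chain & (is.na(d) | d > 2.5)
  # across chains the boundary acts as a break via segment_ids()
  s$break_after[!same_chain] <- FALSE
  s
}

#' Extract a single chain
#'
#' @param s An `ss_structure`.
#' @param chain_id Single chain identifier.
#' @return A single-chain `ss_structure` preserving residue identity.
#' @export
select_chain <- function(s, chain_id) {
  avail <- unique(s$residues$chain)
  if (!chain_id %in% avail)
    stop(sprintf("chain '%s' not found; available chains: %s",
                 chain_id, paste(avail, collapse = ", ")))
  new_ss_structure(s$atom[s$atom$chain == chain_id,
                          setdiff(names(s$atom), "res_idx"), drop = FALSE])
}

#' Renumber residues sequentially
#'
#' Renumbers a single-chain structure `start, start+1, ...` in file order,
#' clearing insertion codes from the working numbering.  The original PDB
#' identifiers are retained and used by the tabular report's absolute
#' residue names.
#'
#' @param s Single-chain `ss_structure`.
#' @param start First residue number (default 1).
#' @return The renumbered structure.
#' @export
renumber_residues <- function(s, start = 1L) {
  if (length(unique(s$residues$chain)) > 1)
    stop("renumber_residues expects a single-chain structure")
  n <- n_residues(s)
  newno <- seq.int(start, length.out = n)
  if (is.null(s$atom$orig_res_seq)) {
    s$atom$orig_res_seq <- s$atom$res_seq
    s$atom$orig_i_code <- s$atom$i_code
  }
  map <- match(s$atom$res_idx, seq_len(n))
  s$atom$res_seq <- newno[map]
  s$atom$i_code <- ""
  s$residues$res_seq <- newno
  s$residues$i_code <- ""
  s
}
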
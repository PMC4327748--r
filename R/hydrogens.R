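# Backbone amide hydrogens.  The hydrogen-bond energy model needs the
# amide H position; crystal structures usually lack hydrogens, in which
# case H is modelled on the bisector-free DSSP convention: 1.0 Angstrom
# from N, along the direction of the preceding peptide C=O bond.

#' Check for backbone amide hydrogens
#'
#' @param s An `ss_structure`.
#' @return `TRUE` if at least one standard residue that can carry a
#'   backbone amide hydrogen (not a chain-first residue, not proline) has
#'   an atom named "H"; the per-residue presence vector is attached as
#'   attribute `"per_residue"`.
#' @export
detect_hydrogens <- function(s) {
  n <- n_residues(s)
  per <- rep(FALSE, n)
  if (n) {
    h <- atom_matrix(s, "H")
    per <- !is.na(h[, 1])
  }
  seg <- segment_ids(s)
  first_of_seg <- c(TRUE, seg[-1] != seg[-n])[seq_len(n)]
  eligible <- s$residues$standard & !first_of_seg & s$residues$res_name != "PRO"
  flag <- any(per & eligible)
  attr(flag, "per_residue") <- per
  flag
}

#' Model missing backbone amide hydrogens
#'
#' For every residue lacking an "H" atom -- except chain-first residues,
#' residues following a chain break, and prolines -- places H at
#' `N(i) + 1.0 * unit(C(i-1) - O(i-1))`.  Residues that already carry an
#' amide H are left untouched, making the operation idempotent.
#'
#' @param s An `ss_structure`.
#' @return The structure with H atoms added; residue indices where H could
#'   not be placed because the preceding residue lacks C or O are attached
#'   as attribute `"no_donor"`.
#' @export
place_amide_hydrogens <- function(s) {
  s <- if (anyNA(s$break_after)) detect_chain_breaks(s) else s
  n <- n_residues(s)
  if (n == 0) return(s)
  seg <- segment_ids(s)
  bb <- bb_coords(s)
  has_h <- !is.na(bb$H[, 1])
  no_donor <- integer(0)
  new_rows <- list()
  for (i in seq_len(n)) {
    if (has_h[i]) next
    if (i == 1 || seg[i] != seg[i - 1]) next       # chain start or after break
    if (s$residues$res_name[i] == "PRO") next
    if (!s$residues$standard[i]) next
    N <- bb$N[i, ]; C <- bb$C[i - 1, ]; O <- bb$O[i - 1, ]
    if (anyNA(N)) next
    if (anyNA(C) || anyNA(O)) {
      no_donor <- c(no_donor, i)
      next
    }
    H <- N + vunit(C - O)
    # insert directly after this residue's N atom
    ridx <- which(s$atom$res_idx == i)
    anchor <- ridx[match("N", s$atom$atom[ridx])]
    if (is.na(anchor)) anchor <- ridx[1]
    row <- s$atom[anchor, , drop = FALSE]
    row$atom <- "H"; row$element <- "H"
    row$x <- H[1]; row$y <- H[2]; row$z <- H[3]
    row$serial <- NA_integer_
    new_rows[[length(new_rows) + 1]] <- list(after = anchor, row = row)
  }
  if (length(new_rows)) {
    pieces <- list()
    prev <- 0
    for (nr in new_rows) {
      pieces[[length(pieces) + 1]] <- s$atom[(prev + 1):nr$after, , drop = FALSE]
      pieces[[length(pieces) + 1]] <- nr$row
      prev <- nr$after
    }
    if (prev < nrow(s$atom))
      pieces[[length(pieces) + 1]] <- s$atom[(prev + 1):nrow(s$atom), , drop = FALSE]
    atom <- do.call(rbind, pieces)
    atom$serial <- seq_len(nrow(atom))
    rownames(atom) <- NULL
    ba <- s$break_after
    s2 <- new_ss_structure(atom[, setdiff(names(atom), "res_idx"), drop = FALSE])
    s2$break_after <- ba
    s2$residues$orig_res_seq <- s$residues$orig_res_seq
    s2$residues$orig_i_code <- s$residues$orig_i_code
    s <- s2
  }
  attr(s, "no_donor") <- no_donor
  s
}
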
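# Deterministic ideal-geometry backbone builders.  These generate the test
# structures with known secondary structure (helix, strand, hairpin) from
# internal coordinates, so no deposited PDB entry is ever needed.
#
# Bond lengths: N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 Angstrom.
# Bond angles: N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7 degrees.

BB_GEOM <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
                a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7)

#' Build a polypeptide backbone from torsion angles
#'
#' Places N/CA/C/O atoms for `n` residues by sequential torsion placement
#' using ideal peptide bond lengths and angles.  The carbonyl oxygen is
#' placed in the CA-C-N(next) plane opposite the nitrogen.
#'
#' @param n Number of residues.
#' @param phi,psi,omega Backbone torsions in degrees; recycled to length
#'   `n`.  `phi[1]` and `psi[n]` only affect virtual placements.
#' @param sequence One-letter sequence (string of length `n`); default
#'   poly-alanine.
#' @param chain Chain identifier.
#' @return An `ss_structure`.
#' @export
build_backbone <- function(n, phi = -57, psi = -47, omega = 180,
                           sequence = NULL, chain = "A") {
  stopifnot(n >= 1)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  if (is.null(sequence)) sequence <- strrep("A", n)
  seq1 <- strsplit(sequence, "")[[1]]
  stopifnot(length(seq1) == n)
  g <- BB_GEOM
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         g$b_c_n, g$a_ca_c_n, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$b_n_ca, g$a_c_n_ca, omega[i])
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  for (i in seq_len(n)) {
    Nn <- if (i < n) N[i + 1, ] else
      place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$a_ca_c_n, psi[i])
    O[i, ] <- C[i, ] + g$b_c_o * vunit(vunit(C[i, ] - Nn) + vunit(C[i, ] - CA[i, ]))
  }
  map3 <- stats::setNames(STANDARD_AA, aa_one_letter(STANDARD_AA))
  res_name <- unname(map3[seq1])
  res_name[is.na(res_name)] <- "UNK"
  atom <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(type = "ATOM", serial = 0L,
               atom = c("N", "CA", "C", "O"), alt = "",
               res_name = res_name[i], chain = chain, res_seq = i,
               i_code = "",
               x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
               y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
               z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
               occ = 1, b = 0,
               element = c("N", "C", "C", "O"), stringsAsFactors = FALSE)
  }))
  atom$serial <- seq_len(nrow(atom))
  new_ss_structure(atom)
}

#' Canonical test structures
#'
#' `make_alpha_helix` builds an ideal right-handed alpha-helix
#' (phi = -57, psi = -47); `make_extended_strand` a fully extended single
#' strand (phi = -139, psi = 135); `make_antiparallel_hairpin` two
#' antiparallel strands of `strand_len` residues joined by a two-residue
#' turn whose torsions were tuned so that the cross-strand N...O distances
#' support Kabsch-Sander hydrogen bonds.
#'
#' @param n,strand_len Number of residues (per strand for the hairpin).
#' @return An `ss_structure`.
#' @export
make_alpha_helix <- function(n) build_backbone(n, phi = -57, psi = -47)

#' @rdname make_alpha_helix
#' @export
make_extended_strand <- function(n) build_backbone(n, phi = -139, psi = 135)

#' @rdname make_alpha_helix
#' @export
make_antiparallel_hairpin <- function(strand_len) {
  stopifnot(strand_len >= 3)
  turn <- HAIRPIN_TURN
  phi <- c(rep(-139, strand_len), turn$phi, rep(-139, strand_len))
  psi <- c(rep(135, strand_len), turn$psi, rep(135, strand_len))
  build_backbone(2 * strand_len + 2, phi = phi, psi = psi)
}

# two-residue connector torsions for the hairpin builder, chosen once by
# scanning turn geometries for the one maximising cross-strand
# Kabsch-Sander bonds (N...O ~ 2.9 A) against the fixed strand torsions
HAIRPIN_TURN <- list(phi = c(45, -180), psi = c(0, -45))
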
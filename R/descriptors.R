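# Per-residue geometric descriptors reported alongside the secondary
# structure summary: backbone torsions phi/psi, the CA virtual-bond
# descriptors kappa and alpha (with chirality), the carbonyl correlation
# TCO, and solvent accessibility.  Undefined values (chain termini and
# breaks) are NA internally and rendered as 360.0 in DSSP-format output.

# helper: TRUE when residues i..j are consecutive within one unbroken segment
span_ok <- function(seg, i, j) {
  if (i < 1 || j > length(seg)) return(FALSE)
  all(seg[i:j] == seg[i])
}

#' Backbone torsion angles phi and psi
#'
#' `phi(i) = dihedral(C(i-1), N(i), CA(i), C(i))`,
#' `psi(i) = dihedral(N(i), CA(i), C(i), N(i+1))`; undefined at chain
#' termini and across chain breaks.
#'
#' @param s An `ss_structure`.
#' @return Data frame with columns `phi`, `psi` (degrees, NA if undefined).
#' @export
phi_psi <- function(s) {
  s <- if (anyNA(s$break_after)) detect_chain_breaks(s) else s
  n <- n_residues(s)
  seg <- segment_ids(s)
  bb <- bb_coords(s)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (span_ok(seg, i - 1, i) &&
        !anyNA(c(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])))
      phi[i] <- dihedral(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    if (span_ok(seg, i, i + 1) &&
        !anyNA(c(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ])))
      psi[i] <- dihedral(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ])
  }
  data.frame(phi = phi, psi = psi)
}

#' Virtual-bond bend angle kappa
#'
#' Angle at CA(i) between the directions from CA(i-2) and towards CA(i+2),
#' in `[0, 180]` degrees; a bend ('S') requires kappa > 70.
#'
#' @param s An `ss_structure`.
#' @return Numeric vector of kappa values (NA if undefined).
#' @export
bend_kappa <- function(s) {
  s <- if (anyNA(s$break_after)) detect_chain_breaks(s) else s
  n <- n_residues(s)
  seg <- segment_ids(s)
  CA <- atom_matrix(s, "CA")
  kap <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!span_ok(seg, i - 2, i + 2)) next
    a <- CA[i, ] - CA[i - 2, ]
    b <- CA[i + 2, ] - CA[i, ]
    if (anyNA(a) || anyNA(b) || vnorm(a) < 1e-9 || vnorm(b) < 1e-9) next
    kap[i] <- vangle(a, b)
  }
  kap
}

#' CA virtual torsion alpha with chirality
#'
#' `alpha(i)` is the dihedral over CA(i-1), CA(i), CA(i+1), CA(i+2);
#' chirality is '+' for alpha in (0, 180], '-' for [-180, 0), ' ' when
#' undefined.
#'
#' @param s An `ss_structure`.
#' @return Data frame with columns `alpha` (degrees, NA if undefined) and
#'   `chirality`.
#' @export
alpha_chirality <- function(s) {
  s <- if (anyNA(s$break_after)) detect_chain_breaks(s) else s
  n <- n_residues(s)
  seg <- segment_ids(s)
  CA <- atom_matrix(s, "CA")
  alp <- rep(NA_real_, n)
  chir <- rep(" ", n)
  for (i in seq_len(n)) {
    if (!span_ok(seg, i - 1, i + 2)) next
    pts <- CA[(i - 1):(i + 2), , drop = FALSE]
    if (anyNA(pts)) next
    alp[i] <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    if (!is.na(alp[i])) chir[i] <- if (alp[i] >= 0) "+" else "-"
  }
  data.frame(alpha = alp, chirality = chir, stringsAsFactors = FALSE)
}

#' Carbonyl direction correlation TCO
#'
#' Cosine of the angle between the C=O bond vectors of residue i and
#' residue i-1.
#'
#' @param s An `ss_structure`.
#' @return Numeric vector (NA if undefined).
#' @export
tco <- function(s) {
  s <- if (anyNA(s$break_after)) detect_chain_breaks(s) else s
  n <- n_residues(s)
  seg <- segment_ids(s)
  bb <- bb_coords(s)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!span_ok(seg, i - 1, i)) next
    v1 <- bb$O[i, ] - bb$C[i, ]
    v0 <- bb$O[i - 1, ] - bb$C[i - 1, ]
    if (anyNA(v1) || anyNA(v0)) next
    out[i] <- sum(v1 * v0) / (vnorm(v1) * vnorm(v0))
  }
  out
}

SR_RADII <- c(C = 1.80, N = 1.65, O = 1.40, S = 1.85)

# deterministic quasi-uniform sphere points (golden-spiral lattice)
sphere_points <- function(m) {
  k <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * k / m)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per residue
#'
#' Shrake-Rupley numerical integration: each heavy atom is covered with a
#' deterministic quasi-uniform point lattice on its solvent-expanded sphere
#' (van der Waals radius + probe), and points inside any neighbouring
#' expanded sphere are occluded.  Radii: C 1.80, N 1.65, O 1.40, S 1.85
#' Angstrom (1.80 for other elements); probe 1.4 Angstrom; hydrogens are
#' excluded.
#'
#' @param s An `ss_structure`.
#' @param probe Probe radius in Angstrom.
#' @param n_points Lattice points per atom.
#' @return Numeric vector of per-residue accessible areas in squared
#'   Angstrom (sum over the residue's heavy atoms).
#' @export
accessibility <- function(s, probe = 1.4, n_points = 960) {
  a <- s$atom[s$atom$element != "H" & s$atom$atom != "H", , drop = FALSE]
  n <- n_residues(s)
  out <- numeric(n)
  if (nrow(a) == 0) return(out)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- SR_RADII[a$element]
  rad[is.na(rad)] <- 1.80
  rexp <- rad + probe
  pts <- sphere_points(n_points)
  acc_atom <- numeric(nrow(a))
  for (k in seq_len(nrow(a))) {
    d2 <- rowSums((xyz - matrix(xyz[k, ], nrow(a), 3, byrow = TRUE))^2)
    nb <- which(d2 < (rexp + rexp[k])^2 & d2 > 1e-12)
    sp <- pts * rexp[k]
    sp <- sp + matrix(xyz[k, ], n_points, 3, byrow = TRUE)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dd <- rowSums((sp[free, , drop = FALSE] -
                       matrix(xyz[j, ], sum(free), 3, byrow = TRUE))^2)
      free[free] <- dd >= rexp[j]^2
    }
    acc_atom[k] <- 4 * pi * rexp[k]^2 * sum(free) / n_points
  }
  tab <- tapply(acc_atom, a$res_idx, sum)
  out[as.integer(names(tab))] <- as.numeric(tab)
  out
}
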
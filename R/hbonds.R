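# Kabsch-Sander electrostatic hydrogen-bond model.  The carbonyl group
# C=O of the acceptor carries partial charges (-q1 on O, +q1 on C) and the
# amide group N-H of the donor (+q2 on H, -q2 on N); the interaction
# energy is
#
#   E = q1 * q2 * (1/r(ON) + 1/r(CH) - 1/r(OH) - 1/r(CN)) * f
#
# with q1 = 0.42 e, q2 = 0.20 e, f = 332, giving E in kcal/mol.  A
# hydrogen bond exists when E < -0.5 kcal/mol.

HB_Q1Q2F <- 0.42 * 0.20 * 332           # 27.888
HB_CUTOFF <- -0.5                       # kcal/mol
HB_E_MIN <- -9.9                        # clamp for pathological geometry
HB_CLASH <- 0.5                         # Angstrom; closer is not a bond
HB_CA_PREFILTER <- 9.0                  # Angstrom CA-CA prescreen

#' Kabsch-Sander hydrogen-bond energy of one acceptor/donor pair
#'
#' @param C,O Acceptor carbonyl carbon and oxygen coordinates (3-vectors).
#' @param N,H Donor amide nitrogen and hydrogen coordinates.
#' @return Energy in kcal/mol, clamped below at -9.9; `NA` when any
#'   defining distance is closer than 0.5 Angstrom (atom clash, treated as
#'   not a bond) or any coordinate is missing.
#' @export
hbond_energy <- function(C, O, N, H) {
  if (anyNA(c(C, O, N, H))) return(NA_real_)
  r_on <- adist(O, N); r_ch <- adist(C, H)
  r_oh <- adist(O, H); r_cn <- adist(C, N)
  if (min(r_on, r_ch, r_oh, r_cn) < HB_CLASH) return(NA_real_)
  e <- HB_Q1Q2F * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  max(e, HB_E_MIN)
}

#' Build the hydrogen-bond table for a structure
#'
#' Computes the directed Kabsch-Sander energy for every ordered residue
#' pair within a 9.0 Angstrom CA-CA prescreen.  Donors must carry an amide
#' hydrogen (prolines and chain-first residues are never donors).
#'
#' @param s An `ss_structure` with hydrogens present or placed.
#' @return An object of class `hbond_table`: list with `energy` (n x n
#'   matrix; `energy[i, j]` is the energy of CO(i) accepting from NH(j)),
#'   `segments`, and per-residue best-partner lists used for reporting.
#' @export
build_hbond_table <- function(s) {
  s <- if (anyNA(s$break_after)) detect_chain_breaks(s) else s
  n <- n_residues(s)
  seg <- segment_ids(s)
  bb <- bb_coords(s)
  E <- matrix(NA_real_, n, n)
  if (n >= 2) {
    ca_ok <- !is.na(bb$CA[, 1])
    can_accept <- !is.na(bb$C[, 1]) & !is.na(bb$O[, 1])
    can_donate <- !is.na(bb$N[, 1]) & !is.na(bb$H[, 1]) &
      s$residues$res_name != "PRO"
    for (i in which(can_accept & ca_ok)) {
      for (j in which(can_donate & ca_ok)) {
        if (i == j) next
        if (adist(bb$CA[i, ], bb$CA[j, ]) > HB_CA_PREFILTER) next
        E[i, j] <- hbond_energy(bb$C[i, ], bb$O[i, ], bb$N[j, ], bb$H[j, ])
      }
    }
  }
  tab <- list(energy = E, segments = seg, n = n)
  class(tab) <- "hbond_table"
  tab
}

#' Hydrogen-bond predicate
#'
#' `TRUE` when CO(i) accepts a hydrogen bond from NH(j): energy below
#' -0.5 kcal/mol and sequence separation `|i - j| >= 2`.
#'
#' @param tab An `hbond_table`.
#' @param i Acceptor residue index (vectorised).
#' @param j Donor residue index (vectorised).
#' @return Logical vector.
#' @export
hb <- function(tab, i, j) {
  n <- tab$n
  ok <- i >= 1 & i <= n & j >= 1 & j <= n & abs(i - j) >= 2
  out <- logical(length(ok))
  idx <- which(ok)
  if (length(idx)) {
    e <- tab$energy[cbind(i[idx], j[idx])]
    out[idx] <- !is.na(e) & e < HB_CUTOFF
  }
  out
}

# best (lowest-energy) bonded partners for reporting: up to two acceptors
# of NH(i) and two donors to CO(i), sorted ascending by energy, earlier
# sequence position first on ties; only pairs satisfying the bond
# predicate (E < -0.5, separation >= 2) qualify
best_partners <- function(tab) {
  n <- tab$n
  pick2 <- function(e, i) {
    cand <- which(!is.na(e) & e < HB_CUTOFF & abs(seq_len(n) - i) >= 2)
    if (!length(cand)) return(list())
    ord <- cand[order(e[cand], cand)]
    ord <- ord[seq_len(min(2, length(ord)))]
    lapply(ord, function(j) list(partner = j, energy = e[j]))
  }
  list(
    nh_acceptors = lapply(seq_len(n), function(i) pick2(tab$energy[, i], i)),
    co_donors = lapply(seq_len(n), function(i) pick2(tab$energy[i, ], i))
  )
}
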
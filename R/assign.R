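# Secondary-structure assignment from the hydrogen-bond table: n-turns,
# helices, beta-bridges, ladders and sheets, bends, and the final
# 8-state summary (H, B, E, G, I, T, S, blank).
#
# A residue's final state follows the priority H > B > E > G > I > T > S.
# Helical states (H, G, I) are only assigned to runs of at least four
# consecutive residues; shorter runs fall back to H-bonded turn (T).

SS_LEVELS <- c("H", "B", "E", "G", "I", "T", "S", " ")

#' n-turn assignment
#'
#' An n-turn at residue i (n = 3, 4, 5) is a hydrogen bond from CO(i) to
#' NH(i+n) whose full span lies in one unbroken chain segment.
#'
#' @param tab An `hbond_table`.
#' @return List with, for each n in 3:5, the logical vector `turn_at`
#'   (turn starting at i), the display marks (`'>'` start, `'<'` end,
#'   `'X'` both, digit inside), and the logical `t_candidate` vector of
#'   residues strictly inside any turn.
#' @export
assign_turns <- function(tab) {
  n <- tab$n
  seg <- tab$segments
  out <- list()
  t_cand <- rep(FALSE, n)
  for (k in 3:5) {
    at <- rep(FALSE, n)
    idx <- seq_len(max(n - k, 0))
    if (length(idx)) {
      ok <- vapply(idx, function(i) all(seg[i:(i + k)] == seg[i]), logical(1))
      at[idx[ok]] <- hb(tab, idx[ok], idx[ok] + k)
    }
    start <- at
    end <- rep(FALSE, n)
    inside <- rep(FALSE, n)
    for (i in which(at)) {
      end[i + k] <- TRUE
      inside[(i + 1):(i + k - 1)] <- TRUE
      t_cand[(i + 1):(i + k - 1)] <- TRUE
    }
    marks <- rep(" ", n)
    marks[inside] <- as.character(k)
    marks[start] <- ">"
    marks[end & !start] <- "<"
    marks[start & end] <- "X"
    out[[as.character(k)]] <- list(turn_at = at, marks = marks)
  }
  out$t_candidate <- t_cand
  out
}

# residues covered by runs shorter than min_len are returned separately so
# they can fall back to 'T'
runs_at_least <- function(flag, min_len = 4) {
  r <- rle(flag)
  keep <- flag
  short <- rep(FALSE, length(flag))
  pos <- cumsum(c(1, r$lengths))
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] < min_len) {
      span <- pos[k]:(pos[k] + r$lengths[k] - 1)
      keep[span] <- FALSE
      short[span] <- TRUE
    }
  }
  list(keep = keep, short = short)
}

#' Helix candidates from overlapping turns
#'
#' A minimal n-helix nucleates at residue i when n-turns start at both
#' i-1 and i, marking residues i..i+n-1.  Candidate runs shorter than
#' four residues are demoted to turn; when a residue qualifies for
#' several helix types the priority is H (alpha) over G (3-10) over I
#' (pi).
#'
#' @param turns Result of [assign_turns()].
#' @param n Number of residues.
#' @return List of logical vectors `H`, `G`, `I` plus `t_extra`
#'   (demoted short runs, turn fallback).
#' @export
assign_helices <- function(turns, n) {
  nucleate <- function(k) {
    at <- turns[[as.character(k)]]$turn_at
    cand <- rep(FALSE, n)
    for (i in which(at)) {
      if (i >= 2 && at[i - 1]) cand[i:(i + k - 1)] <- TRUE
    }
    cand
  }
  t_extra <- rep(FALSE, n)
  hH <- runs_at_least(nucleate(4))
  t_extra <- t_extra | hH$short
  gC <- nucleate(3) & !hH$keep
  hG <- runs_at_least(gC)
  t_extra <- t_extra | hG$short
  iC <- nucleate(5) & !hH$keep & !hG$keep
  hI <- runs_at_least(iC)
  t_extra <- t_extra | hI$short
  list(H = hH$keep, G = hG$keep, I = hI$keep, t_extra = t_extra)
}

#' Find beta-bridges
#'
#' Residues i < j (sequence separation at least 3, with i-1..i+1 and
#' j-1..j+1 each inside one unbroken segment) form a
#' parallel bridge when `HB(i-1, j) & HB(j, i+1)` or
#' `HB(j-1, i) & HB(i, j+1)`, and an antiparallel bridge when
#' `HB(i, j) & HB(j, i)` or `HB(i-1, j+1) & HB(j-1, i+1)`.
#'
#' @param tab An `hbond_table`.
#' @return Data frame with columns `i`, `j`, `type`
#'   ("parallel"/"antiparallel").
#' @export
find_bridges <- function(tab) {
  n <- tab$n
  seg <- tab$segments
  trip_ok <- vapply(seq_len(n), function(i)
    i >= 2 && i <= n - 1 && seg[i - 1] == seg[i] && seg[i] == seg[i + 1],
    logical(1))
  res <- list()
  for (i in seq_len(n)) {
    if (!trip_ok[i]) next
    for (j in seq_len(n)) {
      if (j <= i + 2 || !trip_ok[j]) next
      par <- (hb(tab, i - 1, j) && hb(tab, j, i + 1)) ||
             (hb(tab, j - 1, i) && hb(tab, i, j + 1))
      anti <- (hb(tab, i, j) && hb(tab, j, i)) ||
              (hb(tab, i - 1, j + 1) && hb(tab, j - 1, i + 1))
      if (par || anti)
        res[[length(res) + 1]] <- data.frame(
          i = i, j = j, type = if (par) "parallel" else "antiparallel",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(i = integer(), j = integer(), type = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Group bridges into ladders and sheets
#'
#' Consecutive bridges of the same type (i increasing by one; j increasing
#' for parallel, decreasing for antiparallel) form a ladder; ladders
#' sharing a residue belong to one sheet.  Residues of ladders with at
#' least two bridges are extended-strand candidates ('E'); a one-bridge
#' ladder leaves both residues as isolated-bridge candidates ('B').
#' Ladder letters cycle a-z (lower-case parallel, upper-case
#' antiparallel); sheet labels cycle A-Z.
#'
#' @param bridges Data frame from [find_bridges()].
#' @param n Number of residues.
#' @return List with logical vectors `E`, `B`, integer `bp1`, `bp2`
#'   (partner sequential indices, 0 if none), character `ladder`, `sheet`.
#' @export
build_ladders_sheets <- function(bridges, n) {
  out <- list(E = rep(FALSE, n), B = rep(FALSE, n),
              bp1 = integer(n), bp2 = integer(n),
              ladder = rep(" ", n), sheet = rep(" ", n))
  nb <- nrow(bridges)
  if (nb == 0) return(out)
  ord <- order(bridges$i, bridges$j)
  bridges <- bridges[ord, , drop = FALSE]
  ladder_id <- integer(nb)
  next_id <- 0L
  for (k in seq_len(nb)) {
    ladder_id[k] <- 0L
    for (m in seq_len(k - 1)) {
      same <- bridges$type[m] == bridges$type[k] &&
        bridges$i[k] == bridges$i[m] + 1 &&
        ((bridges$type[k] == "parallel" && bridges$j[k] == bridges$j[m] + 1) ||
         (bridges$type[k] == "antiparallel" && bridges$j[k] == bridges$j[m] - 1))
      if (same) { ladder_id[k] <- ladder_id[m]; break }
    }
    if (ladder_id[k] == 0L) { next_id <- next_id + 1L; ladder_id[k] <- next_id }
  }
  n_lad <- next_id
  # sheet = connected component of ladders sharing a residue
  lad_res <- lapply(seq_len(n_lad), function(id) {
    b <- bridges[ladder_id == id, , drop = FALSE]
    unique(c(b$i, b$j))
  })
  sheet_id <- seq_len(n_lad)
  repeat {
    changed <- FALSE
    for (a in seq_len(n_lad)) for (b in seq_len(n_lad)) {
      if (sheet_id[a] != sheet_id[b] &&
          length(intersect(lad_res[[a]], lad_res[[b]]))) {
        sheet_id[sheet_id == max(sheet_id[a], sheet_id[b])] <-
          min(sheet_id[a], sheet_id[b])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sheet_lab_id <- match(sheet_id, sort(unique(sheet_id)))
  for (id in seq_len(n_lad)) {
    b <- bridges[ladder_id == id, , drop = FALSE]
    resids <- unique(c(b$i, b$j))
    letter <- letters[(id - 1) %% 26 + 1]
    if (b$type[1] == "antiparallel") letter <- toupper(letter)
    slet <- LETTERS[(sheet_lab_id[id] - 1) %% 26 + 1]
    if (nrow(b) >= 2) out$E[resids] <- TRUE else out$B[resids] <- TRUE
    out$ladder[resids] <- letter
    out$sheet[resids] <- slet
    for (k in seq_len(nrow(b))) {
      for (pair in list(c(b$i[k], b$j[k]), c(b$j[k], b$i[k]))) {
        r <- pair[1]; p <- pair[2]
        if (out$bp1[r] == 0) out$bp1[r] <- p
        else if (out$bp2[r] == 0 && out$bp1[r] != p) out$bp2[r] <- p
      }
    }
  }
  # a residue in a >=2-bridge ladder is E even if it also carries an
  # isolated bridge; B marks only residues not promoted to E
  out$B <- out$B & !out$E
  out
}

#' Bend candidates
#'
#' @param kappa Numeric vector of bend angles (degrees).
#' @return Logical vector: TRUE where kappa > 70 (strict); undefined kappa
#'   never bends.
#' @export
assign_bends <- function(kappa) {
  !is.na(kappa) & kappa > 70
}

#' Final 8-state summary from candidate layers
#'
#' Applies the priority H > B > E > G > I > T > S > ' '.
#'
#' @param cand List of logical candidate vectors `H`, `B`, `E`, `G`, `I`,
#'   `T`, `S`, all the same length.
#' @return Character vector of per-residue summary codes.
#' @export
assign_summary <- function(cand) {
  n <- length(cand$H)
  out <- rep(" ", n)
  for (code in rev(c("H", "B", "E", "G", "I", "T", "S"))) {
    lay <- cand[[code]]
    out[lay] <- code
  }
  out
}

#' Full secondary-structure assignment pipeline
#'
#' Runs hydrogen detection/placement, chain-break detection, the
#' hydrogen-bond table, turns, helices, bridges/ladders/sheets, bends and
#' all geometric descriptors, and composes the per-residue summary.
#'
#' @param s An `ss_structure`.
#' @return An object of class `ss_assignment`: a data frame with one row
#'   per residue (columns: `idx`, `chain`, `res_seq`, `i_code`, `aa`,
#'   `ss`, turn marks `t3`/`t4`/`t5`, `bend`, `chirality`, `ladder`,
#'   `sheet`, `bp1`, `bp2`, `acc`, four H-bond partner/energy pairs,
#'   `tco`, `kappa`, `alpha`, `phi`, `psi`, CA coordinates), with the
#'   hydrogen-bond count in attribute `n_hbonds` and the structure in
#'   attribute `structure`.
#' @export
assign_ss <- function(s) {
  s <- detect_chain_breaks(s)
  if (!isTRUE(as.logical(detect_hydrogens(s)))) s <- place_amide_hydrogens(s)
  n <- n_residues(s)
  tab <- build_hbond_table(s)
  turns <- assign_turns(tab)
  hel <- assign_helices(turns, n)
  bridges <- find_bridges(tab)
  lad <- build_ladders_sheets(bridges, n)
  kappa <- bend_kappa(s)
  pp <- phi_psi(s)
  ac <- alpha_chirality(s)
  tc <- tco(s)
  acc <- accessibility(s)
  cand <- list(H = hel$H, B = lad$B, E = lad$E, G = hel$G, I = hel$I,
               T = turns$t_candidate | hel$t_extra,
               S = assign_bends(kappa))
  ss <- assign_summary(cand)
  bp <- best_partners(tab)
  hcol <- function(lst, k, field) {
    vapply(seq_len(n), function(i) {
      e <- lst[[i]]
      if (length(e) >= k) {
        if (field == "p") e[[k]]$partner else e[[k]]$energy
      } else if (field == "p") 0 else 0
    }, numeric(1))
  }
  CA <- atom_matrix(s, "CA")
  out <- data.frame(
    idx = seq_len(n),
    chain = s$residues$chain,
    res_seq = s$residues$res_seq,
    i_code = s$residues$i_code,
    aa = s$residues$one_letter,
    ss = ss,
    t3 = turns[["3"]]$marks, t4 = turns[["4"]]$marks, t5 = turns[["5"]]$marks,
    bend = ifelse(cand$S, "S", " "),
    chirality = ac$chirality,
    ladder = lad$ladder, sheet = lad$sheet,
    bp1 = lad$bp1, bp2 = lad$bp2,
    acc = round(acc),
    nho1_p = as.integer(hcol(bp$nh_acceptors, 1, "p")),
    nho1_e = hcol(bp$nh_acceptors, 1, "e"),
    ohn1_p = as.integer(hcol(bp$co_donors, 1, "p")),
    ohn1_e = hcol(bp$co_donors, 1, "e"),
    nho2_p = as.integer(hcol(bp$nh_acceptors, 2, "p")),
    nho2_e = hcol(bp$nh_acceptors, 2, "e"),
    ohn2_p = as.integer(hcol(bp$co_donors, 2, "p")),
    ohn2_e = hcol(bp$co_donors, 2, "e"),
    tco = tc, kappa = kappa, alpha = ac$alpha,
    phi = pp$phi, psi = pp$psi,
    x_ca = CA[, 1], y_ca = CA[, 2], z_ca = CA[, 3],
    stringsAsFactors = FALSE)
  sep_ok <- abs(row(tab$energy) - col(tab$energy)) >= 2
  attr(out, "n_hbonds") <- sum(tab$energy < HB_CUTOFF & sep_ok, na.rm = TRUE)
  attr(out, "structure") <- s
  class(out) <- c("ss_assignment", "data.frame")
  out
}

#' Collapse an 8-state assignment to three states
#'
#' H, G and I map to "helical"; E to "extended"; B, T, S and blank to
#' "unstructured".
#'
#' @param ss Character vector of 8-state codes, or an `ss_assignment`.
#' @return Character vector of "helical"/"extended"/"unstructured".
#' @export
simplify_ss <- function(ss) {
  if (inherits(ss, "ss_assignment")) ss <- ss$ss
  out <- rep("unstructured", length(ss))
  out[ss %in% c("H", "G", "I")] <- "helical"
  out[ss == "E"] <- "extended"
  out
}

#' Three-state labels from HELIX/SHEET header records
#'
#' Residue ranges listed in HELIX records map to "helical", SHEET ranges
#' to "extended", everything else to "unstructured".  Overlaps resolve
#' helical-first; ranges referencing absent residues are clipped with a
#' warning.
#'
#' @param ss_records List with data frames `helices` and `strands` as
#'   returned by [parse_pdb()].
#' @param s An `ss_structure` (typically a selected chain).
#' @return Character vector of per-residue 3-state labels.
#' @export
map_from_header_records <- function(ss_records, s) {
  n <- n_residues(s)
  out <- rep("unstructured", n)
  key <- res_label(s$residues$chain, s$residues$res_seq, s$residues$i_code)
  apply_ranges <- function(df, label) {
    for (k in seq_len(nrow(df))) {
      a <- match(res_label(df$chain[k], df$start_seq[k], df$start_icode[k]), key)
      b <- match(res_label(df$chain[k], df$end_seq[k], df$end_icode[k]), key)
      if (is.na(a) && is.na(b)) {
        if (df$chain[k] %in% s$residues$chain)
          warning(sprintf("%s record %d-%d not resolvable on chain %s; skipped",
                          label, df$start_seq[k], df$end_seq[k], df$chain[k]))
        next
      }
      if (is.na(a) || is.na(b)) {
        warning(sprintf("%s record %d-%d on chain %s clipped to present residues",
                        label, df$start_seq[k], df$end_seq[k], df$chain[k]))
        inchain <- which(s$residues$chain == df$chain[k] &
                           s$residues$res_seq >= df$start_seq[k] &
                           s$residues$res_seq <= df$end_seq[k])
        if (length(inchain)) out[min(inchain):max(inchain)] <<-
            ifelse(label == "HELIX", "helical", "extended")
        next
      }
      out[a:b] <<- if (label == "HELIX") "helical" else "extended"
    }
  }
  apply_ranges(ss_records$strands, "SHEET")
  apply_ranges(ss_records$helices, "HELIX")  # helical-first precedence: applied last
  out
}
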
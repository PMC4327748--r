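# The assignment core: hydrogen-bond energies and table, turns, helices,
# bridges/ladders/sheets, bends, the summary hierarchy and the 3-state
# simplification.

# synthetic hydrogen-bond table on one unbroken segment
fake_table <- function(n, bonds = list()) {
  e <- matrix(NA_real_, n, n)
  for (b in bonds) e[b[1], b[2]] <- if (length(b) > 2) b[3] else -2.0
  structure(list(energy = e, segments = rep(1L, n), n = n),
            class = "hbond_table")
}

test_that("hbond_energy reproduces hand-computed values", {
  # symmetric cancellation: r(ON) = r(OH) and r(CH) = r(CN) gives exactly 0
  C <- c(0, 0, 0); O <- c(0, 1.23, 0)
  N <- c(2.0, 0.615, 0); H <- N + c(1, 0, 0)
  expect_equal(hbond_energy(C, O, N, H), 0)
  # canonical distances r(ON)=2.9, r(OH)=1.9, r(CH)=r(CN)=3.9:
  # O at origin, H and N on the x axis, C on the H..N perpendicular bisector
  O2 <- c(0, 0, 0); H2 <- c(1.9, 0, 0); N2 <- c(2.9, 0, 0)
  C2 <- c(2.4, -sqrt(3.9^2 - 0.5^2), 0)
  e <- hbond_energy(C2, O2, N2, H2)
  # frozen value from the independent arithmetic oracle
  expect_equal(e, -5.0613428, tolerance = 1e-6)
  expect_equal(e, 27.888 * (1 / 2.9 + 1 / 3.9 - 1 / 1.9 - 1 / 3.9),
               tolerance = 1e-9)
})

test_that("hbond_energy clamps and guards against clashes", {
  C <- c(0, 0, 0); O <- c(0, 1.23, 0)
  # near-coincident O and H: huge negative energy clamps at -9.9
  e <- hbond_energy(C, O, c(2, 1.83, 0), c(0.55, 1.23, 0))
  expect_equal(e, -9.9)
  # any distance below 0.5 A is a clash, not a bond
  expect_true(is.na(hbond_energy(C, O, c(2, 1.23, 0), c(0.3, 1.23, 0))))
  expect_true(is.na(hbond_energy(C, O, c(NA, NA, NA), c(1, 1, 1))))
})

test_that("the bond table reproduces known bonding patterns", {
  helix <- place_amide_hydrogens(make_alpha_helix(12))
  tab <- build_hbond_table(helix)
  expect_true(all(hb(tab, 2:7, 6:11)))        # CO(i) -> NH(i+4)
  strand <- place_amide_hydrogens(make_extended_strand(8))
  tabs <- build_hbond_table(strand)
  ij <- expand.grid(i = 1:8, j = 1:8)
  expect_false(any(hb(tabs, ij$i, ij$j)))
  hp <- place_amide_hydrogens(make_antiparallel_hairpin(5))
  tabh <- build_hbond_table(hp)
  recip <- which(outer(1:12, 1:12, function(i, j)
    hb(tabh, i, j) & hb(tabh, j, i) & i < j - 2), arr.ind = TRUE)
  expect_gte(nrow(recip), 1)                  # narrow antiparallel pairs
})

test_that("prolines and chain-first residues never donate", {
  s <- place_amide_hydrogens(build_backbone(12, phi = -57, psi = -47,
                                            sequence = "AAAAAPAAAAAA"))
  tab <- build_hbond_table(s)
  expect_false(any(hb(tab, 1:12, rep(6, 12))))   # proline at 6
  expect_false(any(hb(tab, 1:12, rep(1, 12))))   # chain-first
})

test_that("n-turns follow the definition and produce the display marks", {
  tab <- fake_table(12, list(c(5, 9)))   # single 4-turn at residue 5
  tu <- assign_turns(tab)
  expect_true(tu[["4"]]$turn_at[5])
  expect_equal(sum(tu[["4"]]$turn_at), 1)
  expect_equal(tu[["4"]]$marks[5], ">")
  expect_equal(tu[["4"]]$marks[9], "<")
  expect_equal(tu[["4"]]$marks[6:8], rep("4", 3))
  expect_equal(which(tu$t_candidate), 6:8)
  # no bonds, no turns
  tu0 <- assign_turns(fake_table(8))
  expect_false(any(tu0[["3"]]$turn_at | tu0[["4"]]$turn_at | tu0[["5"]]$turn_at))
  # a start that is also an end is marked X
  tab2 <- fake_table(14, list(c(3, 7), c(7, 11)))
  tu2 <- assign_turns(tab2)
  expect_equal(tu2[["4"]]$marks[7], "X")
})

test_that("turns never span a chain break", {
  h <- make_alpha_helix(12)
  move <- h$atom$res_idx >= 7
  h$atom$x[move] <- h$atom$x[move] + 50
  a <- assign_ss(h)
  # residues flanking the break cannot belong to any helix, and no
  # 4-turn may start where its span would cross the break (positions 3-6)
  expect_false(any(a$ss[6:7] == "H"))
  expect_false(any(a$t4[3:6] %in% c(">", "X")))
})

test_that("helices nucleate from overlapping turns with a 4-residue minimum", {
  # overlapping 4-turns at 4 and 5: alpha-helix residues 5..8
  tu <- assign_turns(fake_table(12, list(c(4, 8), c(5, 9))))
  hel <- assign_helices(tu, 12)
  expect_equal(which(hel$H), 5:8)
  # a lone pair of overlapping 3-turns gives a 3-residue 3-10 run:
  # below the minimum, demoted to turn, never 'G'
  tu3 <- assign_turns(fake_table(12, list(c(4, 7), c(5, 8))))
  hel3 <- assign_helices(tu3, 12)
  expect_false(any(hel3$G))
  expect_true(all(hel3$t_extra[5:7]))
  # three overlapping 3-turns make a 4-residue 3-10 helix
  tu3b <- assign_turns(fake_table(12, list(c(4, 7), c(5, 8), c(6, 9))))
  expect_equal(which(assign_helices(tu3b, 12)$G), 5:8)
  # no turns, no helices
  hel0 <- assign_helices(assign_turns(fake_table(8)), 8)
  expect_false(any(hel0$H | hel0$G | hel0$I))
})

test_that("no helical summary run shorter than 4 residues is ever produced", {
  fixtures <- list(make_alpha_helix(12), make_alpha_helix(6),
                   make_antiparallel_hairpin(5),
                   build_backbone(16, phi = c(rep(-57, 8), rep(-139, 8)),
                                  psi = c(rep(-47, 8), rep(135, 8))))
  for (s in fixtures) {
    a <- assign_ss(s)
    r <- rle(a$ss)
    bad <- r$values %in% c("H", "G", "I") & r$lengths < 4
    expect_false(any(bad))
  }
})

test_that("bridge patterns respect sequence-separation preconditions", {
  # parallel pattern: HB(i-1, j) and HB(j, i+1) with i = 4, j = 9
  tab <- fake_table(12, list(c(3, 9), c(9, 5)))
  br <- find_bridges(tab)
  expect_equal(nrow(br), 1)
  expect_equal(unlist(br[1, c("i", "j")], use.names = FALSE), c(4, 9))
  expect_equal(br$type, "parallel")
  # antiparallel narrow pattern: HB(i, j) and HB(j, i)
  tab2 <- fake_table(12, list(c(4, 9), c(9, 4)))
  br2 <- find_bridges(tab2)
  expect_equal(br2$type, "antiparallel")
  # |i - j| = 2 candidates are rejected even with reciprocal bonds
  tab3 <- fake_table(12, list(c(4, 6), c(6, 4)))
  expect_equal(nrow(find_bridges(tab3)), 0)
  # an ideal helix has no bridges
  helix <- place_amide_hydrogens(make_alpha_helix(12))
  expect_equal(nrow(find_bridges(build_hbond_table(helix))), 0)
})

test_that("ladders, sheets and bridge partners are consistent on the hairpin", {
  hp <- place_amide_hydrogens(make_antiparallel_hairpin(5))
  tab <- build_hbond_table(hp)
  br <- find_bridges(tab)
  expect_gte(sum(br$type == "antiparallel"), 2)
  lad <- build_ladders_sheets(br, 12)
  expect_true(all(lad$E[c(4, 5, 8, 9)]))
  main <- names(sort(table(lad$ladder[lad$ladder != " "]), decreasing = TRUE))[1]
  expect_true(main %in% LETTERS)          # upper case = antiparallel
  expect_equal(unique(lad$sheet[lad$sheet != " "]), "A")
  # bp1 partners point back at each other
  a <- assign_ss(make_antiparallel_hairpin(5))
  for (i in which(a$bp1 > 0)) {
    p <- a$bp1[i]
    expect_true(i %in% c(a$bp1[p], a$bp2[p]))
  }
})

test_that("an isolated bridge yields B on both residues", {
  tab <- fake_table(14, list(c(4, 10), c(10, 4)))
  br <- find_bridges(tab)
  lad <- build_ladders_sheets(br, 14)
  expect_true(all(lad$B[c(4, 10)]))
  expect_false(any(lad$E))
})

test_that("ladders sharing a strand merge into one sheet", {
  bridges <- data.frame(
    i = c(4, 5, 14, 15), j = c(24, 25, 24, 25),
    type = "parallel", stringsAsFactors = FALSE)
  lad <- build_ladders_sheets(bridges, 30)
  expect_equal(unique(lad$sheet[lad$sheet != " "]), "A")
  lets <- unique(lad$ladder[lad$ladder != " "])
  expect_equal(length(lets), 2)           # two ladders, one sheet
})

test_that("bends require kappa strictly above 70 degrees", {
  expect_equal(assign_bends(c(NA, 0, 69.9, 70.0, 70.1, 90)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("the summary hierarchy resolves multiple candidates", {
  n <- 4
  cand <- list(H = c(TRUE, FALSE, FALSE, FALSE),
               B = c(FALSE, FALSE, FALSE, FALSE),
               E = c(FALSE, TRUE, FALSE, FALSE),
               G = c(FALSE, FALSE, FALSE, FALSE),
               I = c(FALSE, FALSE, FALSE, FALSE),
               T = c(TRUE, FALSE, TRUE, FALSE),
               S = c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(assign_summary(cand), c("H", "E", "T", " "))
})

test_that("the 3-state simplification follows the published mapping", {
  expect_equal(simplify_ss(strsplit("HHHHGGG", "")[[1]]), rep("helical", 7))
  expect_equal(simplify_ss("B"), "unstructured")
  expect_equal(simplify_ss(c("E", "T", "S", " ")),
               c("extended", rep("unstructured", 3)))
  # total surjection preserving length
  all8 <- c("H", "G", "I", "E", "B", "T", "S", " ")
  out <- simplify_ss(all8)
  expect_equal(length(out), 8)
  expect_setequal(unique(out), c("helical", "extended", "unstructured"))
})

test_that("header-record mapping covers ranges with helical precedence", {
  s <- build_backbone(10)
  rec <- parse_pdb(c(helix_record("A", 2, 6), write_pdb(s)))$ss_records
  lab <- map_from_header_records(rec, s)
  expect_equal(lab, c("unstructured", rep("helical", 5), rep("unstructured", 4)))
  # empty record set: everything unstructured
  rec0 <- parse_pdb(write_pdb(s))$ss_records
  expect_equal(unique(map_from_header_records(rec0, s)), "unstructured")
  # overlapping HELIX 4-6 and SHEET 3-5: helical wins on the overlap
  rec2 <- parse_pdb(c(helix_record("A", 4, 6), sheet_record("A", 3, 5),
                      write_pdb(s)))$ss_records
  lab2 <- map_from_header_records(rec2, s)
  expect_equal(lab2[3:6], c("extended", rep("helical", 3)))
})

test_that("assignment is invariant under rigid motion and dies with the bonds", {
  h <- make_alpha_helix(10)
  base <- assign_ss(h)$ss
  for (seed in 4:5) {
    expect_equal(assign_ss(apply_rigid_motion(h, seed))$ss, base)
  }
  # stretching the structure removes all hydrogen bonds: only S and blank
  stretched <- assign_ss(make_extended_strand(10))
  expect_true(all(stretched$ss %in% c("S", " ")))
})

test_that("interior residues of an ideal helix are all H", {
  for (n in c(8, 12)) {
    a <- assign_ss(make_alpha_helix(n))
    expect_true(all(a$ss[3:(n - 2)] == "H"))
  }
  a4 <- assign_ss(make_alpha_helix(4))
  expect_false(any(a4$ss %in% c("E", "H", "G", "I")))
})
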
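# Geometric descriptor calculations: torsions, bend angle, CA virtual
# torsion, carbonyl correlation, solvent accessibility.

test_that("dihedral handles cis, trans and degenerate arrangements", {
  # four points in a plane, cis: both outer bonds on the same side
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, 1, 1)), 0)
  # trans: opposite sides
  expect_equal(abs(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(-1, 0, 1))),
               180)
  # coincident and collinear points are signalled, not NaN
  expect_true(is.na(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))))
  expect_true(is.na(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))))
})

test_that("dihedral matches an independent projection oracle on random input", {
  set.seed(42)
  for (k in 1:1000) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    mine <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    ref <- oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("phi/psi recover the torsions the backbone was built with", {
  for (tor in list(c(-57, -47), c(-139, 135))) {
    s <- build_backbone(8, phi = tor[1], psi = tor[2])
    pp <- phi_psi(s)
    expect_true(all(abs(pp$phi[2:8] - tor[1]) < 0.5))
    expect_true(all(abs(pp$psi[1:7] - tor[2]) < 0.5))
    expect_true(is.na(pp$phi[1]))   # chain-first residue
    expect_true(is.na(pp$psi[8]))   # chain-last residue
  }
})

test_that("phi is undefined after a chain break", {
  s <- build_backbone(8)
  move <- s$atom$res_seq >= 5
  s$atom$x[move] <- s$atom$x[move] + 30
  s <- detect_chain_breaks(s)
  pp <- phi_psi(s)
  expect_true(is.na(pp$phi[5]))
  expect_true(is.na(pp$psi[4]))
  expect_false(is.na(pp$phi[6]))
})

test_that("kappa reproduces constructed CA-trace angles", {
  # straight trace: collinear synthetic CA positions give kappa 0
  s <- make_extended_strand(7)
  CA2 <- matrix(c(0, 0, 0), 7, 3, byrow = TRUE)
  CA2[, 1] <- seq(0, 18, 3)
  for (i in 1:7) {
    idx <- which(s$atom$res_idx == i & s$atom$atom == "CA")
    s$atom[idx, c("x", "y", "z")] <- CA2[i, ]
  }
  # right-angle elbow: CA trace turns 90 degrees at residue 4
  elbow <- s
  CA3 <- CA2
  CA3[5:7, 1] <- CA2[4, 1]
  CA3[5:7, 2] <- c(3, 6, 9)
  for (i in 1:7) {
    idx <- which(elbow$atom$res_idx == i & elbow$atom$atom == "CA")
    elbow$atom[idx, c("x", "y", "z")] <- CA3[i, ]
  }
  ks <- bend_kappa(s)
  ke <- bend_kappa(elbow)
  expect_equal(ks[4], 0, tolerance = 1e-6)
  expect_equal(ke[4], 90, tolerance = 1e-6)
  expect_true(all(is.na(ks[c(1, 2, 6, 7)])))
})

test_that("interior helix kappa equals a direct vector computation", {
  h <- make_alpha_helix(9)
  CA <- sapply(c("x", "y", "z"), function(cc)
    h$atom[h$atom$atom == "CA", cc])
  i <- 5
  a <- CA[i, ] - CA[i - 2, ]
  b <- CA[i + 2, ] - CA[i, ]
  hand <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  kap <- bend_kappa(h)
  expect_equal(kap[i], hand, tolerance = 1e-9)
  expect_lt(max(kap[3:7]) - min(kap[3:7]), 1e-6)  # constant in the interior
})

test_that("alpha chirality is + for right-handed and - for mirrored helices", {
  h <- make_alpha_helix(8)
  ac <- alpha_chirality(h)
  expect_true(all(ac$chirality[2:6] == "+"))
  expect_equal(ac$chirality[c(1, 7, 8)], rep(" ", 3))
  m <- alpha_chirality(mirror_structure(h))
  expect_true(all(m$chirality[2:6] == "-"))
  expect_equal(m$alpha[3], -ac$alpha[3], tolerance = 1e-9)
})

test_that("tco is the carbonyl direction cosine", {
  s <- build_backbone(4)
  # make consecutive C=O vectors exactly parallel, then antiparallel
  bbm <- function(s, nm) {
    a <- s$atom[s$atom$atom == nm, ]
    as.matrix(a[order(a$res_idx), c("x", "y", "z")])
  }
  Cm <- bbm(s, "C")
  par <- s
  for (i in 1:4) {
    idx <- which(par$atom$res_idx == i & par$atom$atom == "O")
    par$atom[idx, c("x", "y", "z")] <- Cm[i, ] + c(0, 0, 1.23)
  }
  expect_equal(tco(par)[2:4], rep(1, 3), tolerance = 1e-9)
  anti <- par
  idx <- which(anti$atom$res_idx == 2 & anti$atom$atom == "O")
  anti$atom[idx, c("x", "y", "z")] <- Cm[2, ] - c(0, 0, 1.23)
  expect_equal(tco(anti)[2], -1, tolerance = 1e-9)
  # interior of an ideal helix: constant, equals the hand dot product
  h <- make_alpha_helix(8)
  Ch <- bbm(h, "C"); Oh <- bbm(h, "O")
  v1 <- Oh[5, ] - Ch[5, ]; v0 <- Oh[4, ] - Ch[4, ]
  hand <- sum(v1 * v0) / sqrt(sum(v1^2) * sum(v0^2))
  expect_equal(tco(h)[5], hand, tolerance = 1e-12)
})

test_that("angles are invariant under rigid motion; mirror flips signed ones", {
  h <- make_alpha_helix(9)
  base_pp <- phi_psi(h); base_k <- bend_kappa(h)
  base_a <- alpha_chirality(h); base_t <- tco(h)
  for (seed in 1:3) {
    r <- apply_rigid_motion(h, seed)
    expect_equal(phi_psi(r)$phi, base_pp$phi, tolerance = 1e-6)
    expect_equal(phi_psi(r)$psi, base_pp$psi, tolerance = 1e-6)
    expect_equal(bend_kappa(r), base_k, tolerance = 1e-6)
    expect_equal(alpha_chirality(r)$alpha, base_a$alpha, tolerance = 1e-6)
    expect_equal(tco(r), base_t, tolerance = 1e-6)
  }
  m <- mirror_structure(h)
  expect_equal(phi_psi(m)$phi, -base_pp$phi, tolerance = 1e-6)
  expect_equal(phi_psi(m)$psi, -base_pp$psi, tolerance = 1e-6)
  expect_equal(alpha_chirality(m)$alpha, -base_a$alpha, tolerance = 1e-6)
  expect_equal(bend_kappa(m), base_k, tolerance = 1e-6)
  expect_equal(tco(m), base_t, tolerance = 1e-6)
})

test_that("accessibility agrees with a high-resolution refinement", {
  g <- build_backbone(1, sequence = "G")
  coarse <- accessibility(g, n_points = 960)
  fine <- accessibility(g, n_points = 10000)
  expect_lt(abs(coarse - fine) / fine, 0.02)
})

test_that("a fully caged atom has zero accessible area", {
  # single N atom at the origin surrounded by a dense shell of carbons
  th <- seq(0, pi, length.out = 12)
  ph <- seq(0, 2 * pi, length.out = 24)
  grid <- expand.grid(th = th, ph = ph)
  shell <- cbind(3 * sin(grid$th) * cos(grid$ph),
                 3 * sin(grid$th) * sin(grid$ph),
                 3 * cos(grid$th))
  atom <- data.frame(
    type = "ATOM", serial = seq_len(nrow(shell) + 1),
    atom = c("N", sprintf("C%d", seq_len(nrow(shell)))), alt = "",
    res_name = "ALA", chain = "A",
    res_seq = c(1L, rep(2L, nrow(shell))), i_code = "",
    x = c(0, shell[, 1]), y = c(0, shell[, 2]), z = c(0, shell[, 3]),
    occ = 1, b = 0,
    element = c("N", rep("C", nrow(shell))), stringsAsFactors = FALSE)
  s <- ssmap:::new_ss_structure(atom)
  acc <- accessibility(s)
  expect_equal(acc[1], 0)
})

test_that("accessibility is translation invariant and monotone in crowding", {
  one <- build_backbone(3)
  far <- one
  far$atom$x <- far$atom$x + 500
  expect_equal(accessibility(one), accessibility(far), tolerance = 1e-9)
  # adding a neighbouring atom can only reduce per-residue areas
  crowded <- one
  extra <- crowded$atom[1, ]
  extra$atom <- "C"; extra$element <- "C"
  extra$res_seq <- 3L
  extra$x <- crowded$atom$x[5] + 2
  crowded$atom <- rbind(crowded$atom[1:nrow(crowded$atom), ], extra)
  crowded <- ssmap:::new_ss_structure(
    crowded$atom[, setdiff(names(crowded$atom), "res_idx")])
  expect_true(all(accessibility(crowded)[1:2] <= accessibility(one)[1:2] + 1e-9))
})
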
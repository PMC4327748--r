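# Independent reference implementations and small utilities used across
# the test files.  The oracles deliberately take a different computational
# route from the package functions they check.

# torsion by explicit projection onto the plane normal to the central
# bond (praxeolitic construction), independent of ssmap::dihedral
oracle_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b0 <- p1 - p2
  b1u <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1u) * b1u
  w <- b2 - sum(b2 * b1u) * b1u
  atan2(sum(cr(b1u, v) * w), sum(v * w)) * 180 / pi
}

# naive per-residue confusion tally
oracle_confusion <- function(ref_ss, query_ss, classes) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (k in seq_along(ref_ss)) {
    m[ref_ss[k], query_ss[k]] <- m[ref_ss[k], query_ss[k]] + 1L
  }
  m
}

# random rigid-body motion of the atom coordinates
apply_rigid_motion <- function(s, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  tr <- rnorm(3, sd = 20)
  xyz <- as.matrix(s$atom[, c("x", "y", "z")]) %*% t(R)
  s$atom$x <- xyz[, 1] + tr[1]
  s$atom$y <- xyz[, 2] + tr[2]
  s$atom$z <- xyz[, 3] + tr[3]
  s
}

mirror_structure <- function(s) {
  s$atom$x <- -s$atom$x
  s
}

# PDB header records resolvable by the parser
helix_record <- function(chain, start, end)
  sprintf("HELIX    1   1 ALA %s %4d  ALA %s %4d  1                                   5",
          chain, start, chain, end)

sheet_record <- function(chain, start, end)
  sprintf("SHEET    1   A 2 ALA %s%4d  ALA %s%4d  0", chain, start, chain, end)

# the DSSP per-class residue counts of the published benchmark set
BENCH_DSSP_COUNTS <- c(None = 5626, B = 321, E = 5730, G = 1305, H = 9822,
                       I = 24, S = 2258, T = 2988)
# matched (query-agreeing) counts of the collapsed 3-state comparison
BENCH_MATCHED_3STATE <- c(unstructured = 10204, helical = 9949, extended = 5342)

# synthetic residue-label tables that reproduce given reference class
# counts and per-class matched counts when cross-tabulated
synthetic_label_pair <- function(ref_counts, matched, other_class) {
  ref <- character(0); query <- character(0)
  for (cl in names(ref_counts)) {
    n <- ref_counts[[cl]]
    nm <- if (!is.null(matched[[cl]])) matched[[cl]] else n
    ref <- c(ref, rep(cl, n))
    query <- c(query, rep(cl, nm), rep(other_class[[cl]], n - nm))
  }
  data.frame(chain = "A", res_seq = seq_along(ref), i_code = "",
             ss = ref, query_ss = query, stringsAsFactors = FALSE)
}
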
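---
title: "Secondary structure assignment: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secondary structure assignment: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmap)
```

## The model

`ssmap` assigns per-residue secondary structure from backbone coordinates
using the Kabsch–Sander electrostatic hydrogen-bond model. The carbonyl
group of an acceptor residue carries partial charges −q1 on O and +q1 on
C (q1 = 0.42 e); the amide group of a donor residue carries +q2 on H and
−q2 on N (q2 = 0.20 e). The interaction energy is evaluated from the four
cross distances,

$$E = q_1 q_2 \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
\frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right) \cdot 332
\ \mathrm{kcal\,mol^{-1}},$$

and a hydrogen bond exists when $E < -0.5$ kcal/mol. The −0.5 cutoff
gives the model its tolerance to coordinate error: a bond at ideal
geometry scores around −3 kcal/mol, so bonds survive sub-Ångström
perturbations of either group.

All higher-level states derive from the bond predicate HB(i, j) — "the
carbonyl of residue *i* accepts from the amide of residue *j*":

* **n-turn** at *i* (n = 3, 4, 5): HB(i, i+n), with the whole span inside
  one unbroken chain segment.
* **Helices**: a minimal n-helix nucleates at *i* when n-turns start at
  both *i−1* and *i*, marking residues *i* … *i+n−1*; 4-turns give H
  (α-helix), 3-turns G (3₁₀), 5-turns I (π).
* **β-bridges** between residues *i* < *j* (separation ≥ 3): the parallel
  patterns HB(i−1, j) ∧ HB(j, i+1) or HB(j−1, i) ∧ HB(i, j+1), and the
  antiparallel patterns HB(i, j) ∧ HB(j, i) or HB(i−1, j+1) ∧
  HB(j−1, i+1). Consecutive bridges of one type form a ladder; ladders
  sharing a residue form a sheet. Residues of ladders with ≥ 2 bridges
  are extended strand (E); a lone bridge leaves both residues as isolated
  bridge (B). A residue belonging to both keeps E.
* **T** marks residues strictly inside any n-turn that are not part of a
  helix; **S** marks bends, κ > 70° (strict), where κ is the angle
  between CA(i)−CA(i−2) and CA(i+2)−CA(i).

### The helix-length rule

Helical states (H, G, I) are kept only for runs of **at least four
consecutive residues**. This intentionally deviates from the original
dictionary, where a single pair of overlapping 3-turns yields a
3-residue 3₁₀ helix: here such a run is demoted to H-bonded turn (T).
The practical consequence is that roughly a seventh of classical G
residues report as T, while H and I are essentially unaffected (the
minimal α run is already 4, the minimal π run 5).

### Assignment hierarchy

When a residue satisfies several definitions, the final summary follows
the priority **H > B > E > G > I > T > S > blank**, and overlapping helix
types resolve H over G over I. The hierarchy order is not uniquely
dictated by the model; this package adopts the conventional dictionary
order, which reproduces the expected interplay of bridge and helix
states (e.g. a bridge inside a helical run stays H).

## Parameters and their defaults

| Parameter | Default | Meaning |
|---|---|---|
| Bond cutoff | −0.5 kcal/mol | minimum energy for a hydrogen bond |
| Energy clamp | −9.9 kcal/mol | floor for pathological geometry, keeps report columns well-formed |
| Clash guard | 0.5 Å | any defining distance below this is an atom clash, never a bond |
| CA–CA prescreen | 9.0 Å | pairs farther apart cannot reach −0.5 kcal/mol with these charges and are skipped |
| N–H length | 1.0 Å | modelled amide hydrogen, along C(i−1)−O(i−1) |
| Chain-break threshold | 2.5 Å | C(i)–N(i+1) beyond this (or missing atoms) breaks the chain; turns, bridges and bonds never span a break |
| Bend threshold | 70° | strict inequality on κ |
| Helix run minimum | 4 residues | the deviation described above |
| ACC probe / points | 1.4 Å / 960 | Shrake–Rupley solvent-accessible surface |
| ACC radii | C 1.80, N 1.65, O 1.40, S 1.85 Å | heavy atoms only; 1.80 for other elements |

Solvent accessibility deserves a caveat: the reference report format
prints an ACC column, but the numerical method behind it is not part of
the hydrogen-bond model. `ssmap` uses Shrake–Rupley integration on a
deterministic golden-spiral point lattice with the radii above. ACC is
therefore informational; agreement with other implementations is
expected only to within their own radius/point choices, and the test
suite checks internal convergence (960 vs 10 000 points within 2 %)
rather than cross-software identity.

## Input handling

PDB parsing is delegated to `bio3d::read.pdb` behind a thin conversion
layer. Only the first MODEL of a multi-model file is read; alternate
locations keep the blank or 'A' conformer; waters are dropped;
non-water HETATM residues within a chain are retained as non-standard
residues (MSE maps to one-letter M, unknowns to X) but participate in
assignment only if N, CA, C and O are all present. Prolines and
chain-first residues never donate. Residue renumbering (from 1) clears
insertion codes from the working numbering while the original PDB
identifiers are retained and used by the tabular report's absolute
residue names.

Two report layouts carry identical content. The fixed-column layout
follows the classic per-residue record (summary at column 17, residue
number in columns 6–10, insertion code 11, chain 12, amino acid 14), so
existing fixed-column parsers can read it; undefined angles render as
360.0. The exact column grid of the whitespace-separated "tabular"
layout is this package's own: the published description of that style
exists only as a figure, so the content (absolute residue names,
absolute H-bond partners), not the byte layout, is the contract; empty
fields print as `-` to keep tokenisation unambiguous.

## Comparison arithmetic

`compare_assignments` cross-tabulates two assignments keyed by
(chain, residue number, insertion code); residues present in only one
report are tallied separately, never guessed. Rows are the reference,
columns the query. The 3-state collapse merges G, H, I into *helical*,
E into *extended* and None, B, S, T into *unstructured*; per-class
agreement is the diagonal count divided by the **reference row total**,
reported to 3 decimals. That denominator choice is what makes the
published 3-state agreement triplet (0.912 / 0.892 / 0.932) follow
exactly from the published class totals and matched counts, which is how
`scripts/acceptance.R` recomputes them.

## What the fixtures emulate — and what they do not

The package builds its own test structures from internal coordinates
(bond lengths N–CA 1.458, CA–C 1.525, C–N 1.329, C=O 1.231 Å; angles
N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA 121.7°), by sequential torsion
placement. The α-helix preset uses φ = −57°, ψ = −47°; the extended
strand φ = −139°, ψ = 135°; the antiparallel hairpin joins two such
strands with a two-residue connector at φ = (45°, −180°),
ψ = (0°, −45°). The connector torsions were chosen once, by scanning
turn geometries for the one whose cross-strand N···O contacts best
support the bond pattern against these exact strand torsions, and are
fixed; the connector's own summary is deliberately unconstrained.

These fixtures are ideal: exact repeating torsions, no side chains
beyond the backbone, no thermal noise, no missing atoms, no alternate
conformers. Passing the suite therefore demonstrates that the
*algorithm* implements the bond/turn/bridge logic correctly — including
its behaviour under rigid motion, mirror reflection, chain breaks and
format round trips — not that assignments on experimental crystal
structures will match another implementation residue-for-residue.
On real data, differences concentrate exactly where the hierarchy and
the helix-length rule bite (B vs E, G vs T).

## Numerical choices

* Torsions use the IUPAC sign convention (cis = 0°, trans = 180°,
  clockwise positive viewed from the second to the third atom);
  degenerate (collinear/coincident) point sets yield an explicit
  undefined value, not NaN propagation.
* Undefined angles at termini and breaks are NA internally, 360.0 in
  fixed-column output.
* Ties between equal-energy bond partners keep the earlier-sequence
  partner, making every output deterministic.
* Ladder letters cycle a–z (parallel lower-case, antiparallel
  upper-case in the report), sheet labels A–Z, both modulo 26.
* The isoelectric point is the unique root of the strictly decreasing
  Henderson–Hasselbalch charge curve on pH 0–14, located to 0.01 pH
  units (pKa defaults: N-term 8.6, C-term 3.6, C 8.5, D 3.65, E 4.25,
  H 6.5, K 10.53, R 12.5, Y 10.07 — the EMBOSS set, configurable).
  ε₂₈₀ counts 5500 per Trp, 1490 per Tyr and 125 per cystine
  (⌊nCys/2⌋ oxidised pairs; a flag switches to reduced cysteines).
  Masses are average residue masses plus one water.
* Distance matrices use pairwise deletion; the identity method returns
  percent identity (100 on the diagonal), the p-distance methods a
  fraction (MEGA-style) or percentage (EMBOSS-style) with a zero
  diagonal — two scales of the same count, and the suite checks
  identity = 100·(1 − p) on every pair.

## Problem sizes

The test and acceptance runs use small fixtures throughout: helices of
4–12 residues, strands of 6–10, hairpins of 8–12, 1000-case random
oracle sweeps for the torsion routines, and label vectors of the
published benchmark's 28 074 residues for the comparison arithmetic.
These sizes exercise every code path (termini, breaks, nucleation
minima, ladder merging) while keeping a full run in well under a minute.

## Known limitations

* No polyproline-II state and no β-bulge special-casing beyond ladder
  connectivity; the 8-state dictionary is the ceiling.
* Isolated bridges adjacent to a ladder are not promoted to E; the
  conservative ladder definition is used.
* mmCIF input, NMR ensembles beyond the first model, and ligand
  chemistry are out of scope.
* ACC is informational (see above); relative accessibility is not
  computed.
* The ClustalW reader accepts the standard interleaved dialect;
  MSF and PSIPRED formats are not parsed.
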
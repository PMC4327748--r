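# Report serialisation.  Two layouts carry the same information:
#  - "dssp": the classic fixed-column per-residue record (summary at
#    column 17, residue number in 6-10, insertion code 11, chain 12,
#    amino acid 14) with relative H-bond partner offsets, so third-party
#    DSSP parsers can read it;
#  - "tabular": whitespace-separated columns referencing residues by
#    absolute name (chain + original residue number + insertion code,
#    e.g. "A52" or "A52A"), with '-' for empty fields so tokenisation is
#    unambiguous.

fmt_angle <- function(x) sprintf("%6.1f", ifelse(is.na(x), 360.0, x))
fmt_tco <- function(x) sprintf("%8.3f", ifelse(is.na(x), 0, x))

#' Write an assignment in classic DSSP layout
#'
#' Emits a short header block (residue, chain and hydrogen-bond counts,
#' zero-filled histogram placeholders) followed by one fixed-width line
#' per residue in file order; chain breaks appear as '!' rows.  Undefined
#' angles are rendered as 360.0.
#'
#' @param a An `ss_assignment`.
#' @param path Optional output file.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_dssp_format <- function(a, path = NULL) {
  s <- attr(a, "structure")
  seg <- segment_ids(s)
  n <- nrow(a)
  nch <- length(unique(a$chain))
  nhb <- attr(a, "n_hbonds")
  hdr <- c(
    "==== SECONDARY STRUCTURE ASSIGNMENT BY HYDROGEN-BOND AND GEOMETRY ANALYSIS ====",
    "REFERENCE KABSCH-SANDER HYDROGEN BOND ENERGY MODEL",
    sprintf("%5d%3d%3d%3d%3d TOTAL NUMBER OF RESIDUES, NUMBER OF CHAINS, TOTAL NUMBER OF SS-BRIDGES(TOTAL,INTRACHAIN,INTERCHAIN)",
            n, nch, 0, 0, 0),
    sprintf("%5d  TOTAL NUMBER OF HYDROGEN BONDS", if (is.null(nhb)) 0 else nhb),
    paste0(paste(rep("    0", 11), collapse = ""), "  HISTOGRAMS (PLACEHOLDER)"),
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA")
  hbf <- function(p, e, i) {
    off <- ifelse(p == 0, 0L, p - i)
    sprintf("%6d,%4.1f", off, e)
  }
  lines <- character(0)
  ln <- 0
  for (i in seq_len(n)) {
    if (i > 1 && seg[i] != seg[i - 1]) {
      ln <- ln + 1
      lines <- c(lines, sprintf("%5d        !%s", ln,
                                if (a$chain[i] != a$chain[i - 1]) "*" else " "))
    }
    ln <- ln + 1
    lines <- c(lines, paste0(
      sprintf("%5d%5d%1s%1s %1s  ", ln, a$res_seq[i],
              substr(paste0(a$i_code[i], " "), 1, 1), a$chain[i], a$aa[i]),
      a$ss[i], a$t3[i], a$t4[i], a$t5[i], a$bend[i], a$chirality[i],
      a$ladder[i], " ",
      sprintf("%4d%4d%1s%4.0f ", a$bp1[i], a$bp2[i], a$sheet[i], a$acc[i]),
      hbf(a$nho1_p[i], a$nho1_e[i], i), hbf(a$ohn1_p[i], a$ohn1_e[i], i),
      hbf(a$nho2_p[i], a$nho2_e[i], i), hbf(a$ohn2_p[i], a$ohn2_e[i], i),
      " ", fmt_tco(a$tco[i]), fmt_angle(a$kappa[i]), fmt_angle(a$alpha[i]),
      fmt_angle(a$phi[i]), fmt_angle(a$psi[i]),
      sprintf(" %6.1f %6.1f %6.1f", a$x_ca[i], a$y_ca[i], a$z_ca[i])))
  }
  out <- c(hdr, lines)
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

#' Write an assignment in whitespace-separated tabular layout
#'
#' Same information as the DSSP layout, but columns are separated by
#' whitespace and residues (including hydrogen-bond partners) are
#' referenced by absolute name: chain identifier plus original PDB
#' residue number and insertion code.  Empty fields are rendered '-'.
#'
#' @param a An `ss_assignment`.
#' @param path Optional output file.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_tabular_format <- function(a, path = NULL) {
  s <- attr(a, "structure")
  n <- nrow(a)
  label <- res_label(a$chain, s$residues$orig_res_seq, s$residues$orig_i_code)
  dash <- function(x) ifelse(is.na(x) | x == " " | x == "", "-", x)
  hbf <- function(p, e) ifelse(p == 0, "-", sprintf("%s:%.1f", label[pmax(p, 1)], e))
  rows <- data.frame(
    RES = label, AA = a$aa, SS = dash(a$ss),
    T3 = dash(a$t3), T4 = dash(a$t4), T5 = dash(a$t5),
    BEND = dash(a$bend), CHIR = dash(a$chirality),
    LADDER = dash(a$ladder), SHEET = dash(a$sheet),
    BP1 = ifelse(a$bp1 == 0, "-", label[pmax(a$bp1, 1)]),
    BP2 = ifelse(a$bp2 == 0, "-", label[pmax(a$bp2, 1)]),
    ACC = sprintf("%d", a$acc),
    NHO1 = hbf(a$nho1_p, a$nho1_e), OHN1 = hbf(a$ohn1_p, a$ohn1_e),
    NHO2 = hbf(a$nho2_p, a$nho2_e), OHN2 = hbf(a$ohn2_p, a$ohn2_e),
    TCO = sprintf("%.3f", ifelse(is.na(a$tco), 0, a$tco)),
    KAPPA = sprintf("%.1f", ifelse(is.na(a$kappa), 360, a$kappa)),
    ALPHA = sprintf("%.1f", ifelse(is.na(a$alpha), 360, a$alpha)),
    PHI = sprintf("%.1f", ifelse(is.na(a$phi), 360, a$phi)),
    PSI = sprintf("%.1f", ifelse(is.na(a$psi), 360, a$psi)),
    XCA = sprintf("%.1f", a$x_ca), YCA = sprintf("%.1f", a$y_ca),
    ZCA = sprintf("%.1f", a$z_ca), stringsAsFactors = FALSE)
  widths <- pmax(nchar(names(rows)),
                 apply(rows, 2, function(col) max(nchar(col))))
  pad <- function(x, w) formatC(x, width = w)
  header <- paste(mapply(pad, names(rows), widths), collapse = "  ")
  padded <- matrix(mapply(pad, rows, widths), nrow = n)
  body <- apply(padded, 1, paste, collapse = "  ")
  out <- c(header, body)
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

#' Parse a DSSP-format report
#'
#' Reads the per-residue summaries from classic fixed-column DSSP text
#' (as produced by the DSSP web service or by [write_dssp_format()]).
#' Chain-break ('!') rows are skipped; lower-case amino-acid letters
#' (disulphide-bonded cysteines in the DSSP convention) map to 'C'.
#'
#' @param text Character vector of lines, a single string with newlines,
#'   or a file path.
#' @return Data frame with columns `chain`, `res_seq`, `i_code`, `aa`,
#'   `ss`.
#' @export
parse_dssp_format <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  hdr <- grep("^  #  RESIDUE AA STRUCTURE", text)
  if (!length(hdr)) stop("not a DSSP-format report: missing '  #  RESIDUE AA STRUCTURE' header")
  rows <- text[seq.int(hdr[1] + 1, length.out = length(text) - hdr[1])]
  rows <- rows[nzchar(trimws(rows))]
  aa <- substr(rows, 14, 14)
  keep <- aa != "!"
  rows <- rows[keep]
  if (any(nchar(rows) < 17))
    stop(sprintf("short data row at line %d of the record block",
                 which(nchar(rows) < 17)[1]))
  aa <- substr(rows, 14, 14)
  aa[aa %in% letters] <- "C"
  data.frame(
    chain = substr(rows, 12, 12),
    res_seq = as.integer(substr(rows, 6, 10)),
    i_code = trimws(substr(rows, 11, 11)),
    aa = aa,
    ss = substr(rows, 17, 17),
    stringsAsFactors = FALSE)
}

#' Parse a tabular-format report
#'
#' Reads back the whitespace-separated layout written by
#' [write_tabular_format()], recovering residue identifiers, amino acids
#' and summaries.
#'
#' @param text Character vector of lines, a single string, or a file path.
#' @return Data frame with columns `chain`, `res_seq`, `i_code`, `aa`,
#'   `ss`.
#' @export
parse_tabular_format <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- text[nzchar(trimws(text))]
  toks <- strsplit(trimws(text), "[[:space:]]+")
  hdr <- toks[[1]]
  if (hdr[1] != "RES" || !"SS" %in% hdr)
    stop("not a tabular-format report: missing RES/SS header")
  ss_col <- match("SS", hdr)
  aa_col <- match("AA", hdr)
  rows <- toks[-1]
  ref <- vapply(rows, `[`, character(1), 1)
  m <- regmatches(ref, regexec("^(.)(-?[0-9]+)([A-Za-z]?)$", ref))
  data.frame(
    chain = vapply(m, `[`, character(1), 2),
    res_seq = as.integer(vapply(m, `[`, character(1), 3)),
    i_code = vapply(m, `[`, character(1), 4),
    aa = vapply(rows, `[`, character(1), aa_col),
    ss = sub("^-$", " ", vapply(rows, `[`, character(1), ss_col)),
    stringsAsFactors = FALSE)
}
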
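# Feature alphabets and per-residue class tables.

#' Feature alphabets
#'
#' The five parallel character alphabets used by the scoring matrices:
#' amino acid identity (20 letters), charge (`+`, `N`, `-`), hydropathy
#' (`ζ` hydrophilic, `M` neutral, `Φ` hydrophobic), secondary
#' structure (`C` chain/coil, `E` beta-strand, `H` helix) and relative
#' solvent accessibility discretized `0` (buried) to `9` (exposed).
#'
#' @param feature One of `"aa"`, `"charge"`, `"hydropathy"`, `"ss"`, `"rsa"`.
#' @return Character vector of single characters, in canonical order.
#' @export
feature_alphabet <- function(feature) {
  feature <- match.arg(feature, LYSO_FEATURES)
  switch(feature,
    aa         = AA_ALPHABET20,
    charge     = c("+", "N", "-"),
    hydropathy = c("\u03b6", "M", "\u03a6"),
    ss         = c("C", "E", "H"),
    rsa        = as.character(0:9)
  )
}

#' @rdname feature_alphabet
#' @export
LYSO_FEATURES <- c("aa", "charge", "hydropathy", "ss", "rsa")

#' The 20 canonical amino-acid letters
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Window geometry: 8 residues P4..P1 | P1'..P4', scissile bond between
# positions 4 and 5 of the window.
WINDOW_SIZE <- 8L
WINDOW_POSITIONS <- c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")

#' Residue charge classes
#'
#' Side-chain charge class per canonical residue: D and E negative, K, R
#' and H positive (histidine is weakly basic and grouped with the
#' positives), everything else neutral. The table is data, not code: pass
#' a modified copy to [encode_charge()] to override class membership.
#'
#' @return A data.frame with columns `residue` and `class`.
#' @export
lyso_charge_table <- function() {
  cls <- rep("N", length(AA_ALPHABET20))
  names(cls) <- AA_ALPHABET20
  cls[c("D", "E")] <- "-"
  cls[c("K", "R", "H")] <- "+"
  data.frame(residue = AA_ALPHABET20, class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Residue hydropathy classes
#'
#' Three-way hydropathy split (Kyte-Doolittle-like): hydrophobic
#' (`Φ`) A, C, F, I, L, M, V, W; neutral (`M`) G, H, P, S, T, Y;
#' hydrophilic (`ζ`) D, E, K, N, Q, R. This is a reconstruction of a
#' vendor property table and is deliberately overridable, see
#' [encode_hydropathy()].
#'
#' @return A data.frame with columns `residue` and `class`.
#' @export
lyso_hydropathy_table <- function() {
  cls <- character(length(AA_ALPHABET20))
  names(cls) <- AA_ALPHABET20
  cls[c("A", "C", "F", "I", "L", "M", "V", "W")] <- "\u03a6"
  cls[c("G", "H", "P", "S", "T", "Y")] <- "M"
  cls[c("D", "E", "K", "N", "Q", "R")] <- "\u03b6"
  data.frame(residue = AA_ALPHABET20, class = unname(cls),
             stringsAsFactors = FALSE)
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# validate that a string only uses `alphabet`; error names first offender
check_alphabet <- function(x, alphabet, what) {
  cs <- chars(x)
  bad <- which(!(cs %in% alphabet))
  if (length(bad)) {
    stop(sprintf(
      "invalid %s character '%s' at position %d (allowed: %s)",
      what, cs[bad[1]], bad[1], paste(alphabet, collapse = "")),
      call. = FALSE)
  }
  invisible(cs)
}

map_classes <- function(residues, table, what) {
  cls <- table$class
  names(cls) <- table$residue
  cs <- chars(residues)
  bad <- which(!(cs %in% names(cls)))
  if (length(bad)) {
    stop(sprintf("invalid %s character '%s' at position %d",
                 what, cs[bad[1]], bad[1]), call. = FALSE)
  }
  paste(cls[cs], collapse = "")
}

#' Encode residue charge track
#'
#' Maps an amino-acid string to its per-residue charge classes.
#'
#' @param residues Amino-acid string (canonical 20-letter alphabet).
#' @param table Class table as returned by [lyso_charge_table()].
#' @return A string over `+`, `N`, `-` of the same length.
#' @examples
#' encode_charge("DKA") # "-+N"
#' @export
encode_charge <- function(residues, table = lyso_charge_table()) {
  map_classes(residues, table, "amino-acid")
}

#' Encode residue hydropathy track
#'
#' Maps an amino-acid string to its per-residue hydropathy classes.
#'
#' @param residues Amino-acid string (canonical 20-letter alphabet).
#' @param table Class table as returned by [lyso_hydropathy_table()].
#' @return A string over `ζ`, `M`, `Φ` of the same length.
#' @export
encode_hydropathy <- function(residues, table = lyso_hydropathy_table()) {
  map_classes(residues, table, "amino-acid")
}
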
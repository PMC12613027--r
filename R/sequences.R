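# Annotated sequences, feature tracks and window extraction.

#' Construct an annotated protein sequence
#'
#' Bundles a protein sequence with optional per-residue secondary-structure
#' (`C`/`E`/`H`) and solvent-accessibility (`0`-`9`) tracks. Structural
#' annotations are always computed externally (e.g. by a structure
#' predictor) and consumed here as plain character tracks.
#'
#' @param id Sequence identifier.
#' @param residues Amino-acid string. By default only the 20 canonical
#'   letters are accepted; with `permissive = TRUE` other letters are kept
#'   but any scoring window containing one is skipped downstream.
#' @param ss Optional secondary-structure string over `C`, `E`, `H`.
#' @param rsa Optional solvent-accessibility digit string over `0`-`9`.
#' @param permissive Accept non-canonical residue letters (B, J, O, U, X, Z).
#' @return An object of class `annotated_sequence` with fields `id`,
#'   `residues`, `ss`, `rsa`.
#' @export
annotated_sequence <- function(id, residues, ss = NULL, rsa = NULL,
                               permissive = FALSE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("empty sequence for '", id, "'", call. = FALSE)
  if (permissive) {
    check_alphabet(residues, c(AA_ALPHABET20, "B", "J", "O", "U", "X", "Z"),
                   "amino-acid")
  } else {
    check_alphabet(residues, AA_ALPHABET20, "amino-acid")
  }
  obj <- structure(
    list(id = id, residues = residues, ss = NULL, rsa = NULL,
         permissive = permissive),
    class = "annotated_sequence")
  if (!is.null(ss) || !is.null(rsa)) obj <- attach_structure(obj, ss, rsa)
  obj
}

#' @export
print.annotated_sequence <- function(x, ...) {
  cat(sprintf("<annotated_sequence> %s (%d aa%s%s)\n", x$id,
              nchar(x$residues),
              if (!is.null(x$ss)) ", ss" else "",
              if (!is.null(x$rsa)) ", rsa" else ""))
  invisible(x)
}

#' @export
length.annotated_sequence <- function(x) nchar(x$residues)

#' Attach structural annotation tracks to a sequence
#'
#' @param seq An [annotated_sequence()].
#' @param ss Secondary-structure string over `C`, `E`, `H`; `NULL` to leave
#'   the existing track untouched.
#' @param rsa Solvent-accessibility digit string; `NULL` likewise.
#' @return The sequence with the tracks populated.
#' @export
attach_structure <- function(seq, ss = NULL, rsa = NULL) {
  stopifnot(inherits(seq, "annotated_sequence"))
  L <- nchar(seq$residues)
  if (!is.null(ss)) {
    if (nchar(ss) != L) {
      stop(sprintf("annotation mismatch for '%s': ss length %d != sequence length %d",
                   seq$id, nchar(ss), L), call. = FALSE)
    }
    check_alphabet(ss, feature_alphabet("ss"), "secondary-structure")
    seq$ss <- ss
  }
  if (!is.null(rsa)) {
    if (nchar(rsa) != L) {
      stop(sprintf("annotation mismatch for '%s': rsa length %d != sequence length %d",
                   seq$id, nchar(rsa), L), call. = FALSE)
    }
    check_alphabet(rsa, feature_alphabet("rsa"), "solvent-accessibility")
    seq$rsa <- rsa
  }
  seq
}

#' Encode the feature tracks of a sequence
#'
#' Produces the parallel character tracks used by the scoring matrices.
#' The `aa` track is the sequence itself; `charge` and `hydropathy` are
#' pure functions of the residues; `ss` and `rsa` require the structural
#' annotations to be attached.
#'
#' @param seq An [annotated_sequence()].
#' @param features Character vector of features to encode (subset of
#'   [LYSO_FEATURES]).
#' @return Named list of strings, one per feature, each the same length as
#'   the sequence.
#' @export
encode_tracks <- function(seq, features = LYSO_FEATURES) {
  stopifnot(inherits(seq, "annotated_sequence"))
  features <- match.arg(features, LYSO_FEATURES, several.ok = TRUE)
  out <- list()
  for (f in features) {
    out[[f]] <- switch(f,
      aa = seq$residues,
      charge = encode_permissive(seq$residues, encode_charge),
      hydropathy = encode_permissive(seq$residues, encode_hydropathy),
      ss = seq$ss %||% stop(sprintf(
        "missing annotation: sequence '%s' has no secondary-structure track",
        seq$id), call. = FALSE),
      rsa = seq$rsa %||% stop(sprintf(
        "missing annotation: sequence '%s' has no solvent-accessibility track",
        seq$id), call. = FALSE)
    )
  }
  out
}

# encode charge/hydropathy, carrying non-canonical letters through as-is so
# that window skipping (not the encoder) decides their fate
encode_permissive <- function(residues, encoder) {
  cs <- chars(residues)
  canon <- cs %in% AA_ALPHABET20
  if (all(canon)) return(encoder(residues))
  enc <- cs
  enc[canon] <- chars(encoder(paste(cs[canon], collapse = "")))
  paste(enc, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the P4-P4' window around a candidate scissile bond
#'
#' P1 is the 1-based index of the residue immediately N-terminal to the
#' scissile bond; the window covers positions `p1 - 3` to `p1 + 4`
#' (P4..P1 then P1'..P4'). Terminal positions where the full window does
#' not fit yield `NA`: scoring is defined only on complete windows, with
#' no padding.
#'
#' @param track A character string (any feature track) or an
#'   [annotated_sequence()] (its residue track is used).
#' @param p1 1-based index, `1 <= p1 <= nchar(track)`.
#' @return The 8-character window, or `NA_character_` if it does not fit.
#' @export
extract_window <- function(track, p1) {
  if (inherits(track, "annotated_sequence")) track <- track$residues
  L <- nchar(track)
  if (p1 < 1L || p1 > L) {
    stop(sprintf("p1 = %d out of sequence bounds [1, %d]", p1, L),
         call. = FALSE)
  }
  if (p1 < 4L || p1 > L - 4L) return(NA_character_)
  substr(track, p1 - 3L, p1 + 4L)
}

#' Candidate P1 positions carrying a full window
#'
#' @param L Sequence length (or an [annotated_sequence()]).
#' @return Integer vector `4:(L-4)`, empty when `L < 8`.
#' @export
full_window_positions <- function(L) {
  if (inherits(L, "annotated_sequence")) L <- nchar(L$residues)
  if (L < WINDOW_SIZE) return(integer(0))
  4:(L - 4L)
}

# vectorized window extraction: windows at each p1 as a character vector
windows_at <- function(track, p1s) {
  vapply(p1s, function(p) substr(track, p - 3L, p + 4L), character(1))
}
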
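# Consensus cleavage patterns for low-substrate proteases.
#
# Pattern dialect: eight position tokens P4/P3/P2/P1 | P1'/P2'/P3'/P4',
# '/'-separated, scissile bond marked by '|' (a stray '=' is accepted as a
# synonym). Token forms: 'x' wildcard; a run of residue letters is an
# allowed-set; 'x[^RK]', '[^RK]' or 'x(not R or K)' is an excluded-set.

#' Parse a consensus cleavage pattern
#'
#' @param text Pattern string, e.g. `"EG/VIL/x/LF|x/AV/x/VF"`.
#' @param protease Optional protease (gene) name carried on the object.
#' @return A `cleavage_pattern`: list with `protease`, `positions` (eight
#'   constraints, each `list(type, residues)` with `type` one of `"any"`,
#'   `"allowed"`, `"excluded"`), and `source` (the verbatim text).
#' @export
parse_pattern <- function(text, protease = "") {
  stopifnot(is.character(text), length(text) == 1L)
  norm <- gsub("=", "|", text, fixed = TRUE)
  norm <- gsub("[[:space:]]+", "", norm)
  halves <- strsplit(norm, "|", fixed = TRUE)[[1]]
  if (length(halves) != 2L) {
    stop("pattern syntax: expected exactly one scissile-bond marker '|' in '",
         text, "'", call. = FALSE)
  }
  toks <- c(strsplit(halves[1], "/", fixed = TRUE)[[1]],
            strsplit(halves[2], "/", fixed = TRUE)[[1]])
  if (length(toks) != 8L) {
    stop(sprintf("pattern syntax: expected 8 position tokens, got %d in '%s'",
                 length(toks), text), call. = FALSE)
  }
  positions <- lapply(toks, parse_pattern_token, pattern = text)
  names(positions) <- WINDOW_POSITIONS
  structure(list(protease = protease, positions = positions, source = text),
            class = "cleavage_pattern")
}

parse_pattern_token <- function(tok, pattern) {
  if (!nzchar(tok)) {
    stop("pattern syntax: empty position token in '", pattern, "'",
         call. = FALSE)
  }
  if (tok == "x") return(list(type = "any", residues = character(0)))
  # bracket or "(notAorB)" exclusion forms, with or without leading 'x'
  m <- regmatches(tok, regexec("^x?\\[\\^([A-Z]+)\\]$", tok))[[1]]
  if (length(m) == 2L) {
    res <- chars(m[2])
  } else {
    m <- regmatches(tok, regexec("^x?\\(not([A-Zor]+)\\)$", tok))[[1]]
    if (length(m) == 2L) {
      res <- strsplit(m[2], "or", fixed = TRUE)[[1]]
    } else if (grepl("^[A-Z]+$", tok)) {
      res <- unique(chars(tok))
      bad <- setdiff(res, AA_ALPHABET20)
      if (length(bad)) {
        stop(sprintf("pattern syntax: illegal residue letter '%s' in token '%s'",
                     bad[1], tok), call. = FALSE)
      }
      return(list(type = "allowed", residues = res))
    } else {
      stop("pattern syntax: cannot parse position token '", tok, "' in '",
           pattern, "'", call. = FALSE)
    }
  }
  res <- unique(res)
  bad <- setdiff(res, AA_ALPHABET20)
  if (length(bad) || !length(res)) {
    stop(sprintf("pattern syntax: illegal excluded-set token '%s'", tok),
         call. = FALSE)
  }
  list(type = "excluded", residues = res)
}

#' @export
format.cleavage_pattern <- function(x, ...) {
  tok <- vapply(x$positions, function(p) {
    switch(p$type,
      any = "x",
      allowed = paste(p$residues, collapse = ""),
      excluded = sprintf("x[^%s]", paste(p$residues, collapse = "")))
  }, character(1))
  paste0(paste(tok[1:4], collapse = "/"), "|", paste(tok[5:8], collapse = "/"))
}

#' @export
print.cleavage_pattern <- function(x, ...) {
  cat(sprintf("<cleavage_pattern> %s %s\n",
              if (nzchar(x$protease)) x$protease else "(unnamed)",
              format(x)))
  invisible(x)
}

# per-position logical membership over the 20-letter alphabet
pattern_masks <- function(pattern) {
  lapply(pattern$positions, function(p) {
    ok <- switch(p$type,
      any = rep(TRUE, 20L),
      allowed = AA_ALPHABET20 %in% p$residues,
      excluded = !(AA_ALPHABET20 %in% p$residues))
    names(ok) <- AA_ALPHABET20
    ok
  })
}

#' Match a cleavage pattern against a sequence
#'
#' Scans every candidate P1 carrying a full P4-P4' window and reports the
#' positions whose window satisfies all eight constraints. Matches may
#' overlap. Windows containing non-canonical residue letters never match.
#'
#' @param pattern A [parse_pattern()] result.
#' @param seq An [annotated_sequence()] or plain amino-acid string.
#' @return data.frame with columns `protease`, `p1`, `window`, ordered by
#'   `p1`.
#' @export
match_pattern <- function(pattern, seq) {
  stopifnot(inherits(pattern, "cleavage_pattern"))
  residues <- if (inherits(seq, "annotated_sequence")) seq$residues
              else toupper(seq)
  p1s <- full_window_positions(nchar(residues))
  empty <- data.frame(protease = character(0), p1 = integer(0),
                      window = character(0), stringsAsFactors = FALSE)
  if (!length(p1s)) return(empty)
  wins <- windows_at(residues, p1s)
  chmat <- matrix(unlist(strsplit(wins, "", fixed = TRUE), use.names = FALSE),
                  ncol = WINDOW_SIZE, byrow = TRUE)
  masks <- pattern_masks(pattern)
  ok <- rep(TRUE, length(p1s))
  for (p in seq_len(WINDOW_SIZE)) {
    m <- masks[[p]][chmat[, p]]
    m[is.na(m)] <- FALSE           # non-canonical letter: window skipped
    ok <- ok & m
  }
  data.frame(protease = rep(pattern$protease, sum(ok)), p1 = p1s[ok],
             window = wins[ok], stringsAsFactors = FALSE)
}

#' The packaged phagolysosomal endoprotease registry
#'
#' Seventeen endoproteases, each handled by exactly one mechanism:
#' `pattern` (consensus cleavage pattern, for proteases with few known
#' substrates) or `pssm` (scoring-matrix model trained from substrate
#' data). The registry ships as an editable TSV under
#' `inst/extdata/protease_registry.tsv`.
#'
#' @param path Override the packaged registry file.
#' @return data.frame with columns `gene`, `mechanism`, `pattern_text`.
#' @export
protease_registry <- function(path = system.file("extdata",
                                                 "protease_registry.tsv",
                                                 package = "lysocleave")) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("gene", "mechanism", "pattern_text") %in% names(reg)))
  if (any(reg$mechanism == "pssm" & nzchar(reg$pattern_text))) {
    stop("registry integrity: a pssm protease must not carry a pattern",
         call. = FALSE)
  }
  if (any(reg$mechanism == "pattern" & !nzchar(reg$pattern_text))) {
    stop("registry integrity: a pattern protease must carry a pattern",
         call. = FALSE)
  }
  reg
}

#' Parsed patterns for all pattern-mechanism proteases in the registry
#'
#' @param registry A [protease_registry()] data.frame.
#' @return Named list of `cleavage_pattern` objects.
#' @export
registry_patterns <- function(registry = protease_registry()) {
  rows <- registry[registry$mechanism == "pattern", , drop = FALSE]
  pats <- Map(parse_pattern, rows$pattern_text, rows$gene)
  names(pats) <- rows$gene
  pats
}
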
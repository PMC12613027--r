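# Shared fixtures, all built in code.

# deterministic random amino-acid string
rand_aa <- function(n, alphabet = AA_ALPHABET20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# independent brute-force PSSM recomputation (count / divide / log2),
# deliberately naive and separate from the package's vectorized path
brute_pssm_raw <- function(windows, tracks, feature = "aa") {
  alphabet <- feature_alphabet(feature)
  all_chars <- unlist(strsplit(tracks, ""))
  bg <- sapply(alphabet, function(ch) sum(all_chars == ch) / length(all_chars))
  n <- length(windows)
  pfm <- matrix(0, length(alphabet), 8, dimnames = list(alphabet, NULL))
  for (w in windows) {
    cs <- strsplit(w, "")[[1]]
    for (p in 1:8) pfm[cs[p], p] <- pfm[cs[p], p] + 1 / n
  }
  raw <- matrix(NA_real_, length(alphabet), 8, dimnames = list(alphabet, NULL))
  for (ch in alphabet) {
    for (p in 1:8) {
      if (pfm[ch, p] > 0 && bg[[ch]] > 0) {
        raw[ch, p] <- log2(pfm[ch, p] / bg[[ch]])
      }
    }
  }
  raw[is.na(raw)] <- min(raw, na.rm = TRUE)
  raw
}

# brute-force pattern matcher: test all 8 set memberships at every position
brute_match <- function(pattern, residues) {
  L <- nchar(residues)
  if (L < 8) return(integer(0))
  hits <- integer(0)
  for (p1 in 4:(L - 4)) {
    win <- strsplit(substr(residues, p1 - 3, p1 + 4), "")[[1]]
    ok <- TRUE
    for (j in 1:8) {
      cons <- pattern$positions[[j]]
      ok <- ok && switch(cons$type,
        any = win[j] %in% AA_ALPHABET20,
        allowed = win[j] %in% cons$residues,
        excluded = win[j] %in% AA_ALPHABET20 && !(win[j] %in% cons$residues))
      if (!ok) break
    }
    if (ok) hits <- c(hits, p1)
  }
  hits
}

# brute-force greedy homology clustering over an explicit identity matrix
brute_homology_reps <- function(substrates, threshold) {
  n <- length(substrates)
  if (!n) return(integer(0))
  lens <- sapply(substrates, function(s) nchar(s$residues))
  ord <- order(-lens)
  reps <- integer(0)
  for (i in ord) {
    hit <- FALSE
    for (r in reps) {
      a <- substrates[[i]]$residues; b <- substrates[[r]]$residues
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = {
          m <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
          diag(m) <- 1; m
        }, gapOpening = 0, gapExtension = 1, type = "global")
      if (Biostrings::nmatch(al) / min(nchar(a), nchar(b)) > threshold) {
        hit <- TRUE; break
      }
    }
    if (!hit) reps <- c(reps, i)
  }
  sort(reps)
}

# tiny annotated substrate for digestion/encoding tests
tiny_substrate <- function(id = "tiny") {
  substrate_record(id, "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
                   p1_sites = c(8L, 16L),
                   ss = paste(rep(c("C", "E", "H"), each = 11), collapse = ""),
                   rsa = paste(rep(0:9, length.out = 33), collapse = ""))
}
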
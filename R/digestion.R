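# Digestion simulation: complete, partial and sequential fragment
# generation, plus peptide mass and isoelectric-point annotation.

# build the fragment data.frame for [start, end] pairs on a parent sequence
make_fragments <- function(seq, starts, ends, steps = NULL, scores = NULL) {
  id <- if (inherits(seq, "annotated_sequence")) seq$id else "seq"
  residues <- if (inherits(seq, "annotated_sequence")) seq$residues else seq
  n <- length(starts)
  df <- data.frame(
    parent_id = rep(id, n), start = as.integer(starts),
    end = as.integer(ends), length = as.integer(ends - starts + 1L),
    sequence = substring(residues, starts, ends),
    stringsAsFactors = FALSE)
  df$score <- if (is.null(scores)) rep(NA_real_, n) else scores
  df$steps <- if (is.null(steps)) vector("list", n) else steps
  class(df) <- c("fragment_table", "data.frame")
  df
}

check_cut_positions <- function(p1_positions, L) {
  p <- as.integer(p1_positions)
  if (anyDuplicated(p)) {
    warning("duplicate cut positions collapsed", call. = FALSE)
    p <- unique(p)
  }
  p <- sort(p)
  if (length(p) && (min(p) < 1L || max(p) > L - 1L)) {
    stop(sprintf("cut position out of range [1, %d]", L - 1L), call. = FALSE)
  }
  p
}

#' Complete digestion at a set of cut sites
#'
#' Cutting after each P1 position partitions the sequence: `n` cuts yield
#' exactly `n + 1` fragments whose concatenation restores the input.
#'
#' @param seq An [annotated_sequence()] or plain amino-acid string.
#' @param p1_positions Cut positions (P1 indices, bond cut between `p1`
#'   and `p1 + 1`), each in `[1, L - 1]`.
#' @return A `fragment_table` data.frame: `parent_id`, `start`, `end`,
#'   `length`, `sequence`, `score`, `steps` (1-based inclusive
#'   coordinates).
#' @export
complete_fragments <- function(seq, p1_positions = integer(0)) {
  residues <- if (inherits(seq, "annotated_sequence")) seq$residues else seq
  L <- nchar(residues)
  p <- check_cut_positions(p1_positions, L)
  starts <- c(1L, p + 1L)
  ends <- c(p, L)
  make_fragments(seq, starts, ends)
}

#' Partial digestion: all combinations of adjacent segments
#'
#' Enumerates every concatenation of one or more consecutive
#' complete-digest segments, modelling incompletely digested material:
#' for `n` cuts this is `(n + 1)(n + 2) / 2` fragments, including the
#' `n + 1` complete fragments and the full-length sequence.
#'
#' @inheritParams complete_fragments
#' @return A `fragment_table`, ordered by `start` then `end`.
#' @export
partial_fragments <- function(seq, p1_positions = integer(0)) {
  residues <- if (inherits(seq, "annotated_sequence")) seq$residues else seq
  L <- nchar(residues)
  p <- check_cut_positions(p1_positions, L)
  bounds_start <- c(1L, p + 1L)
  bounds_end <- c(p, L)
  k <- length(bounds_start)
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  starts <- bounds_start[idx[, "row"]]
  ends <- bounds_end[idx[, "col"]]
  o <- order(starts, ends)
  make_fragments(seq, starts[o], ends[o])
}

#' Define a sequential digestion plan
#'
#' @param proteases Non-empty list of [scoring_model()] and/or
#'   [parse_pattern()] objects, in the order the proteases act.
#' @param min_length Minimum fragment length retained in the final output
#'   (default 4, about the smallest epitope-like peptide).
#' @param partial Also emit adjacent-segment partial combinations when the
#'   plan is used for single-step digestion.
#' @return A `digest_plan` object.
#' @export
digest_plan <- function(proteases, min_length = 4L, partial = FALSE) {
  if (!is.list(proteases) || !length(proteases)) {
    stop("config error: protease plan must be a non-empty list", call. = FALSE)
  }
  ok <- vapply(proteases, function(p) {
    inherits(p, "scoring_model") || inherits(p, "cleavage_pattern")
  }, logical(1))
  if (!all(ok)) {
    stop("config error: plan entries must be scoring models or cleavage patterns",
         call. = FALSE)
  }
  stopifnot(min_length >= 1L)
  structure(list(proteases = proteases, min_length = as.integer(min_length),
                 partial = isTRUE(partial)),
            class = "digest_plan")
}

protease_name <- function(p) {
  if (inherits(p, "scoring_model")) p$protease
  else if (nzchar(p$protease)) p$protease else "pattern"
}

# called sites of one protease on one (sub)sequence; returns data.frame
# p1 (local), score
called_sites <- function(protease, seq) {
  if (inherits(protease, "cleavage_pattern")) {
    m <- match_pattern(protease, seq)
    data.frame(p1 = m$p1, score = rep(NA_real_, nrow(m)))
  } else {
    sc <- suppressMessages(scan_sequence(protease, seq))
    hit <- sc[sc$positive, , drop = FALSE]
    data.frame(p1 = hit$p1, score = hit$final)
  }
}

slice_annotated <- function(seq, start, end, suffix = NULL) {
  id <- if (is.null(suffix)) seq$id else paste0(seq$id, suffix)
  annotated_sequence(
    id, substr(seq$residues, start, end),
    ss = if (!is.null(seq$ss)) substr(seq$ss, start, end),
    rsa = if (!is.null(seq$rsa)) substr(seq$rsa, start, end),
    permissive = isTRUE(seq$permissive))
}

#' Sequential (ordered) digestion
#'
#' Simulates stepwise proteolysis: the first protease digests the whole
#' sequence completely at all its called sites; each later protease acts
#' independently on every fragment left by the previous step, seeing only
#' windows fully contained in that fragment — a site whose P4-P4' window
#' straddles an earlier cut no longer exists. After the last step,
#' fragments shorter than `min_length` are discarded; the survivors are
#' non-overlapping and, together with the discarded ones, tile the input.
#' Structural annotation tracks are sliced along with the sequence.
#'
#' @param seq An [annotated_sequence()].
#' @param plan A [digest_plan()].
#' @return A `fragment_table` with `steps` (list-column of
#'   `(protease, p1, score)` producing events per fragment boundary) and
#'   `score` (mean final score of the scored sites that produced the
#'   fragment's boundaries; `NA` when no scored site did).
#' @export
sequential_digest <- function(seq, plan) {
  stopifnot(inherits(seq, "annotated_sequence"), inherits(plan, "digest_plan"))
  L <- nchar(seq$residues)
  # fragments as [start, end] with the cut events at their two boundaries
  # (NULL at the parent sequence's own termini)
  frags <- list(list(start = 1L, end = L, left = NULL, right = NULL))
  for (k in seq_along(plan$proteases)) {
    protease <- plan$proteases[[k]]
    pname <- protease_name(protease)
    nxt <- list()
    for (fr in frags) {
      sub <- slice_annotated(seq, fr$start, fr$end)
      sites <- called_sites(protease, sub)
      if (!nrow(sites)) {
        nxt[[length(nxt) + 1L]] <- fr
        next
      }
      cuts <- sites$p1                      # local coordinates
      events <- lapply(seq_along(cuts), function(j) {
        list(protease = pname, step = k, p1 = fr$start + cuts[j] - 1L,
             score = sites$score[j])
      })
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, fr$end - fr$start + 1L)
      for (j in seq_along(starts)) {
        nxt[[length(nxt) + 1L]] <- list(
          start = fr$start + starts[j] - 1L,
          end = fr$start + ends[j] - 1L,
          left = if (j > 1L) events[[j - 1L]] else fr$left,
          right = if (j <= length(cuts)) events[[j]] else fr$right)
      }
    }
    frags <- nxt
  }
  keep <- vapply(frags, function(fr) fr$end - fr$start + 1L >= plan$min_length,
                 logical(1))
  frags <- frags[keep]
  if (!length(frags)) return(make_fragments(seq, integer(0), integer(0)))
  starts <- vapply(frags, `[[`, integer(1), "start")
  ends <- vapply(frags, `[[`, integer(1), "end")
  steps <- lapply(frags, function(fr) {
    evs <- Filter(Negate(is.null), list(fr$left, fr$right))
    if (!length(evs)) return(NULL)
    do.call(rbind, lapply(evs, function(e) {
      data.frame(protease = e$protease, step = e$step, p1 = e$p1,
                 score = e$score, stringsAsFactors = FALSE)
    }))
  })
  scores <- vapply(steps, function(s) {
    if (is.null(s) || all(is.na(s$score))) NA_real_
    else mean(s$score, na.rm = TRUE)
  }, numeric(1))
  o <- order(starts)
  make_fragments(seq, starts[o], ends[o], steps = steps[o],
                 scores = scores[o])
}

#' Annotate a fragment table with mass and isoelectric point
#'
#' @param fragments A `fragment_table`.
#' @param monoisotopic Use monoisotopic residue masses.
#' @return The table with `mw` (daltons) and `pi` (pH units) columns.
#' @export
annotate_fragments <- function(fragments, monoisotopic = FALSE) {
  canon <- grepl(sprintf("^[%s]+$", paste(AA_ALPHABET20, collapse = "")),
                 fragments$sequence)
  fragments$mw <- NA_real_
  fragments$pi <- NA_real_
  fragments$mw[canon] <- vapply(fragments$sequence[canon], peptide_mw,
                                numeric(1), monoisotopic = monoisotopic,
                                USE.NAMES = FALSE)
  fragments$pi[canon] <- vapply(fragments$sequence[canon], peptide_pi,
                                numeric(1), USE.NAMES = FALSE)
  fragments
}

# average and monoisotopic residue masses (Da) and the mass of water
RESIDUE_MASS_AVG <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
RESIDUE_MASS_MONO <- c(
  A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259, F = 147.06841,
  G = 57.02146, H = 137.05891, I = 113.08406, K = 128.09496, L = 113.08406,
  M = 131.04049, N = 114.04293, P = 97.05276, Q = 128.05858, R = 156.10111,
  S = 87.03203, T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333)
WATER_MASS_AVG <- 18.01524
WATER_MASS_MONO <- 18.010565

#' Peptide molecular weight
#'
#' Sum of residue masses plus one water.
#'
#' @param sequence Non-empty canonical amino-acid string.
#' @param monoisotopic Use monoisotopic instead of average masses.
#' @return Mass in daltons.
#' @export
peptide_mw <- function(sequence, monoisotopic = FALSE) {
  if (!nzchar(sequence)) stop("empty peptide has no mass", call. = FALSE)
  cs <- check_alphabet(sequence, AA_ALPHABET20, "amino-acid")
  masses <- if (monoisotopic) RESIDUE_MASS_MONO else RESIDUE_MASS_AVG
  water <- if (monoisotopic) WATER_MASS_MONO else WATER_MASS_AVG
  sum(masses[cs]) + water
}

# EMBOSS-style pKa values; the table is an argument so it can be swapped
LYSO_PKA_DEFAULT <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

#' Default pKa table for isoelectric-point calculation
#' @return List with `nterm`, `cterm`, `positive`, `negative` pKa values.
#' @export
lyso_pka_table <- function() LYSO_PKA_DEFAULT

#' Peptide net charge at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and ionizable side chains.
#'
#' @param sequence Canonical amino-acid string.
#' @param ph pH value(s).
#' @param pka pKa table, see [lyso_pka_table()].
#' @return Net charge (same length as `ph`).
#' @export
peptide_charge <- function(sequence, ph, pka = lyso_pka_table()) {
  cs <- check_alphabet(sequence, AA_ALPHABET20, "amino-acid")
  counts <- table(factor(cs, levels = AA_ALPHABET20))
  vapply(ph, function(p) {
    pos <- 1 / (1 + 10^(p - pka$nterm)) +
      sum(vapply(names(pka$positive), function(r) {
        counts[[r]] / (1 + 10^(p - pka$positive[[r]]))
      }, numeric(1)))
    neg <- 1 / (1 + 10^(pka$cterm - p)) +
      sum(vapply(names(pka$negative), function(r) {
        counts[[r]] / (1 + 10^(pka$negative[[r]] - p))
      }, numeric(1)))
    pos - neg
  }, numeric(1))
}

#' Peptide isoelectric point
#'
#' Bisection root of the net-charge curve over a packaged pKa table.
#'
#' @param sequence Non-empty canonical amino-acid string.
#' @param pka pKa table, see [lyso_pka_table()].
#' @param tol Convergence tolerance in pH units (default 0.01).
#' @return The pH at which net charge is (approximately) zero.
#' @export
peptide_pi <- function(sequence, pka = lyso_pka_table(), tol = 0.01) {
  if (!nzchar(sequence)) stop("empty peptide has no pI", call. = FALSE)
  lo <- 0; hi <- 14
  # net charge is monotone decreasing in pH
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (peptide_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
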
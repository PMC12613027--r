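# Synthetic substrate corpora with planted cleavage motifs, so that every
# other module is testable without downloading substrate databases.

#' Define a planted cleavage motif
#'
#' A motif is one categorical residue distribution per window position
#' P4..P4' plus a structural bias at the site (a favoured secondary
#' structure class and a solvent-accessibility range, emulating the
#' observation that cleavage sites tend to sit in beta-strand, buried
#' context) and an expected site density.
#'
#' @param position_probs 20 x 8 matrix of per-position residue
#'   probabilities (rows = [AA_ALPHABET20], columns = P4..P4'); each
#'   column must sum to 1.
#' @param ss_class Secondary-structure class planted at site windows.
#' @param rsa_range Inclusive integer range of accessibility digits
#'   planted at site windows.
#' @param density Expected planted sites per 100 residues.
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(position_probs, ss_class = "E", rsa_range = c(0L, 3L),
                       density = 2) {
  stopifnot(is.matrix(position_probs),
            nrow(position_probs) == 20L, ncol(position_probs) == WINDOW_SIZE,
            all(abs(colSums(position_probs) - 1) < 1e-9),
            all(position_probs >= 0),
            ss_class %in% feature_alphabet("ss"),
            length(rsa_range) == 2L, rsa_range[1] <= rsa_range[2],
            all(rsa_range %in% 0:9), density > 0)
  rownames(position_probs) <- AA_ALPHABET20
  colnames(position_probs) <- WINDOW_POSITIONS
  structure(list(position_probs = position_probs, ss_class = ss_class,
                 rsa_range = as.integer(rsa_range), density = density),
            class = "motif_spec")
}

# helper: build one positional distribution from named point masses,
# spreading the remainder uniformly over the other residues
position_dist <- function(masses = NULL) {
  p <- rep(0, 20)
  names(p) <- AA_ALPHABET20
  if (is.null(masses) || !length(masses)) return(p + 1 / 20)
  stopifnot(all(names(masses) %in% AA_ALPHABET20), sum(masses) <= 1)
  p[names(masses)] <- masses
  rest <- setdiff(AA_ALPHABET20, names(masses))
  p[rest] <- (1 - sum(masses)) / length(rest)
  p
}

#' An aspartic-cathepsin-like default motif
#'
#' Emulates the positional preferences reported for cathepsin D: a strong
#' hydrophobic P1 (consensus F, then L and W), cysteine and acidic
#' residues enriched at P2, I/F at P1', beta-strand and low solvent
#' accessibility at the site. The P1 consensus residue carries a 0.6
#' point mass (a "strong" motif); the remaining positions are uniform.
#'
#' @param density Expected sites per 100 residues.
#' @return A [motif_spec()].
#' @export
ctsd_like_motif <- function(density = 2) {
  probs <- cbind(
    position_dist(),                                   # P4
    position_dist(),                                   # P3
    position_dist(c(C = 0.30, D = 0.15, E = 0.15)),    # P2
    position_dist(c(F = 0.60, L = 0.20, W = 0.12)),    # P1
    position_dist(c(I = 0.35, F = 0.35)),              # P1'
    position_dist(),                                   # P2'
    position_dist(),                                   # P3'
    position_dist())                                   # P4'
  motif_spec(probs, ss_class = "E", rsa_range = c(0L, 3L), density = density)
}

sample_chars <- function(n, alphabet, prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

#' Generate a synthetic substrate corpus with planted cleavage sites
#'
#' Sequences are sampled i.i.d. from the background composition; planted
#' sites overwrite eight consecutive positions with draws from the motif's
#' positional distributions. Sites never overlap another site's window and
#' always sit at least four residues from either terminus, so every
#' recorded P1 carries a full window. Secondary-structure and
#' accessibility tracks follow a uniform background except over planted
#' windows, which carry the motif's structural bias.
#'
#' @param n_substrates Number of substrates (>= 1).
#' @param length_range Inclusive range of substrate lengths (>= 16).
#' @param motif A [motif_spec()].
#' @param background Residue probabilities over [AA_ALPHABET20]
#'   (default uniform, which keeps matrix oracles hand-checkable).
#' @param seed Integer seed; generation is byte-reproducible.
#' @param annotate Also generate ss/rsa tracks.
#' @return List of [substrate_record()]s with attributes `motif`, `seed`,
#'   `background`; class `synthetic_corpus`.
#' @export
generate_corpus <- function(n_substrates, length_range = c(150L, 250L),
                            motif = ctsd_like_motif(), background = NULL,
                            seed = 0L, annotate = TRUE) {
  stopifnot(n_substrates >= 1, length_range[1] >= 16L,
            inherits(motif, "motif_spec"))
  if (is.null(background)) background <- rep(1 / 20, 20)
  stopifnot(length(background) == 20L, abs(sum(background) - 1) < 1e-9)
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  ss_bg <- feature_alphabet("ss")
  rsa_bg <- feature_alphabet("rsa")
  subs <- vector("list", n_substrates)
  for (i in seq_len(n_substrates)) {
    # sample.int form: robust when the length range is a single value
    L <- length_range[1] + sample.int(length_range[2] - length_range[1] + 1L,
                                      1L) - 1L
    res <- sample(AA_ALPHABET20, L, replace = TRUE, prob = background)
    ss <- sample(ss_bg, L, replace = TRUE)
    rsa <- sample(rsa_bg, L, replace = TRUE)
    n_sites <- max(1L, stats::rpois(1, motif$density * L / 100))
    # candidate P1 positions with a full window, placed greedily without
    # window overlap
    cand <- full_window_positions(L)
    p1s <- integer(0)
    for (s in seq_len(n_sites)) {
      avail <- cand[vapply(cand, function(p) {
        !length(p1s) || all(abs(p1s - p) >= WINDOW_SIZE)
      }, logical(1))]
      if (!length(avail)) {
        if (!length(p1s)) {
          stop("generation error: motif density too high to place sites",
               call. = FALSE)
        }
        break
      }
      p <- if (length(avail) == 1L) avail else sample(avail, 1L)
      p1s <- c(p1s, p)
      win_idx <- (p - 3L):(p + 4L)
      res[win_idx] <- vapply(seq_len(WINDOW_SIZE), function(j) {
        sample(AA_ALPHABET20, 1L, prob = motif$position_probs[, j])
      }, character(1))
      ss[win_idx] <- motif$ss_class
      rsa[win_idx] <- as.character(sample(motif$rsa_range[1]:motif$rsa_range[2],
                                          WINDOW_SIZE, replace = TRUE))
    }
    subs[[i]] <- substrate_record(
      sprintf("synth%04d", i), paste(res, collapse = ""),
      p1_sites = sort(p1s),
      ss = if (annotate) paste(ss, collapse = ""),
      rsa = if (annotate) paste(rsa, collapse = ""))
  }
  structure(subs, motif = motif, seed = seed, background = background,
            class = c("synthetic_corpus", "list"))
}

#' Corrupt the site labels of a corpus
#'
#' Stress-tests threshold calibration under label noise: drops a seeded
#' fraction of true site labels and adds spurious labels at random
#' non-site full-window positions. The uncorrupted ground truth is kept in
#' the `truth` attribute.
#'
#' @param corpus A [generate_corpus()] result.
#' @param drop_fraction Fraction of true labels removed, in `[0, 1)`.
#' @param spurious_fraction Spurious labels added, as a fraction of the
#'   original label count, in `[0, 1)`.
#' @param seed Integer seed.
#' @return The corpus with corrupted `p1_sites`; attribute `truth` holds
#'   the original per-substrate site lists.
#' @export
corrupt_sites <- function(corpus, drop_fraction = 0, spurious_fraction = 0,
                          seed = 0L) {
  stopifnot(drop_fraction >= 0, drop_fraction < 1,
            spurious_fraction >= 0, spurious_fraction < 1)
  truth <- lapply(corpus, `[[`, "p1_sites")
  names(truth) <- vapply(corpus, `[[`, character(1), "id")
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  all_sites <- unlist(lapply(seq_along(corpus), function(i) {
    rep(i, length(corpus[[i]]$p1_sites))
  }))
  n_total <- length(all_sites)
  n_drop <- as.integer(round(drop_fraction * n_total))
  n_spur <- as.integer(round(spurious_fraction * n_total))
  if (n_drop > 0L) {
    drop_global <- sample.int(n_total, n_drop)
    for (i in unique(all_sites[drop_global])) {
      local_idx <- which(all_sites == i)
      kill <- match(intersect(drop_global, local_idx), local_idx)
      corpus[[i]]$p1_sites <- corpus[[i]]$p1_sites[-kill]
    }
  }
  if (n_spur > 0L) {
    targets <- sample.int(length(corpus), n_spur, replace = TRUE)
    for (i in targets) {
      cand <- setdiff(full_window_positions(corpus[[i]]),
                      corpus[[i]]$p1_sites)
      if (length(cand)) {
        corpus[[i]]$p1_sites <- sort(c(corpus[[i]]$p1_sites,
                                       if (length(cand) == 1L) cand
                                       else sample(cand, 1L)))
      }
    }
  }
  attr(corpus, "truth") <- truth
  corpus
}
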
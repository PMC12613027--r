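# Training protocol: substrate records, homology filtering, substrate-level
# splitting, labelled window sets, model training and evaluation metrics.

#' Construct a substrate record
#'
#' A full-length substrate protein with its experimentally annotated P1
#' cleavage positions (the residue N-terminal to each scissile bond) and
#' optional structural annotation tracks.
#'
#' @param id Substrate identifier.
#' @param sequence Amino-acid string.
#' @param p1_sites Integer vector of 1-based P1 indices, each in
#'   `[1, L - 1]`; duplicates are collapsed.
#' @param ss,rsa Optional annotation tracks (see [annotated_sequence()]).
#' @return Object of class `substrate_record`.
#' @export
substrate_record <- function(id, sequence, p1_sites = integer(0),
                             ss = NULL, rsa = NULL) {
  seq <- annotated_sequence(id, sequence, ss = ss, rsa = rsa)
  p1_sites <- sort(unique(as.integer(p1_sites)))
  L <- nchar(seq$residues)
  if (length(p1_sites) && (min(p1_sites) < 1L || max(p1_sites) > L - 1L)) {
    stop(sprintf("substrate '%s': P1 sites must lie in [1, %d]", id, L - 1L),
         call. = FALSE)
  }
  structure(c(unclass(seq), list(p1_sites = p1_sites)),
            class = c("substrate_record", "annotated_sequence"))
}

#' @export
print.substrate_record <- function(x, ...) {
  cat(sprintf("<substrate_record> %s (%d aa, %d sites%s)\n", x$id,
              nchar(x$residues), length(x$p1_sites),
              if (!is.null(x$ss)) ", annotated" else ""))
  invisible(x)
}

# pairwise identity: exact matches in a global alignment (match 1,
# mismatch 0, gap -1 per position) divided by the shorter length
pair_identity <- local({
  submat <- NULL
  function(a, b) {
    if (is.null(submat)) {
      letters <- c(AA_ALPHABET20, "B", "J", "O", "U", "X", "Z")
      m <- matrix(0, length(letters), length(letters),
                  dimnames = list(letters, letters))
      diag(m) <- 1
      submat <<- m
    }
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 1,
      type = "global")
    Biostrings::nmatch(al) / min(nchar(a), nchar(b))
  }
})

#' Greedy homology filtering of a substrate corpus
#'
#' Removes redundant substrates: sequences are visited longest-first, each
#' joining the first existing cluster whose representative it matches
#' above the identity threshold, otherwise founding a new cluster.
#' Identity is the number of exact matches in a global alignment divided
#' by the length of the shorter sequence. Returns the representatives
#' (cluster founders), mirroring redundancy removal at a standard 70%
#' homology threshold.
#'
#' @param substrates List of [substrate_record()]s.
#' @param identity_threshold Fraction in `(0, 1]`; a substrate is dropped
#'   when its identity to a representative exceeds this value.
#' @return The representative subset, in input order.
#' @export
homology_filter <- function(substrates, identity_threshold = 0.70) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (!length(substrates)) return(substrates)
  lens <- vapply(substrates, function(s) nchar(s$residues), integer(1))
  ord <- order(-lens)
  reps <- integer(0)
  for (i in ord) {
    joined <- FALSE
    for (r in reps) {
      if (pair_identity(substrates[[i]]$residues,
                        substrates[[r]]$residues) > identity_threshold) {
        joined <- TRUE
        break
      }
    }
    if (!joined) reps <- c(reps, i)
  }
  substrates[sort(reps)]
}

#' Substrate-level train/test split
#'
#' Partitions the corpus by substrate identity so that no window of a test
#' substrate can appear in training. The test set size is
#' `max(1, floor(n * (1 - train_fraction)))`.
#'
#' @param substrates List of [substrate_record()]s (at least 2).
#' @param train_fraction Fraction assigned to training (default 0.9).
#' @param seed Integer seed; the split is reproducible.
#' @return List with elements `train` and `test`.
#' @export
split_substrates <- function(substrates, train_fraction = 0.9, seed = 0L) {
  n <- length(substrates)
  if (n < 2L) stop("split error: need at least 2 substrates", call. = FALSE)
  stopifnot(train_fraction > 0, train_fraction < 1)
  n_test <- max(1L, as.integer(floor(n * (1 - train_fraction) + 1e-9)))
  old_seed <- globalenv()$.Random.seed
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  test_idx <- sort(sample.int(n, n_test))
  list(train = substrates[setdiff(seq_len(n), test_idx)],
       test = substrates[test_idx])
}

# window bundles (per enabled feature) at given p1 positions of a substrate
substrate_bundles <- function(substrate, p1s, features) {
  tracks <- encode_tracks(substrate, features)
  lapply(tracks, windows_at, p1s = p1s)
}

concat_bundles <- function(bundle_list, features) {
  out <- lapply(features, function(f) {
    unlist(lapply(bundle_list, `[[`, f), use.names = FALSE) %||% character(0)
  })
  names(out) <- features
  out
}

#' Assemble labelled window sets from annotated substrates
#'
#' Positives are the windows at annotated P1 sites (full-window positions
#' only; sites too close to a terminus are dropped with a warning).
#' `set1` keeps every other full-window position as a negative, reflecting
#' the true class imbalance; `set2` down-samples the negatives to a
#' `ratio`:1 negative:positive ratio (sampling without replacement,
#' seeded; if fewer negatives exist they are all kept with a warning).
#'
#' @param substrates List of [substrate_record()]s with P1 annotations.
#' @param mode `"set1"` (unbalanced) or `"set2"` (under-sampled).
#' @param features Enabled features (windows are extracted per feature).
#' @param ratio Negative:positive ratio for `set2`.
#' @param seed Integer seed for the under-sampling.
#' @return Class `labelled_window_set`: list with `positives`, `negatives`
#'   (window bundles), `provenance`, `seed`.
#' @export
build_labelled_sets <- function(substrates, mode = c("set1", "set2"),
                                features = "aa", ratio = 3L, seed = 0L) {
  mode <- match.arg(mode)
  pos_b <- list(); neg_b <- list()
  n_dropped <- 0L
  for (s in substrates) {
    cand <- full_window_positions(s)
    pos_p1 <- intersect(s$p1_sites, cand)
    n_dropped <- n_dropped + length(setdiff(s$p1_sites, cand))
    neg_p1 <- setdiff(cand, s$p1_sites)
    if (length(pos_p1)) {
      pos_b[[length(pos_b) + 1L]] <- substrate_bundles(s, pos_p1, features)
    }
    if (length(neg_p1)) {
      neg_b[[length(neg_b) + 1L]] <- substrate_bundles(s, neg_p1, features)
    }
  }
  if (n_dropped) {
    warning(n_dropped, " annotated site(s) without a full window dropped",
            call. = FALSE)
  }
  positives <- concat_bundles(pos_b, features)
  negatives <- concat_bundles(neg_b, features)
  npos <- length(positives[[1]])
  if (!npos) {
    stop("insufficient data: no positive full-window site in corpus",
         call. = FALSE)
  }
  if (mode == "set2") {
    nneg <- length(negatives[[1]])
    want <- ratio * npos
    if (nneg > want) {
      old_seed <- globalenv()$.Random.seed
      on.exit(restore_seed(old_seed), add = TRUE)
      set.seed(seed)
      keep <- sort(sample.int(nneg, want))
      negatives <- lapply(negatives, `[`, keep)
    } else if (nneg < want) {
      warning(sprintf("only %d negatives available for a %d:1 ratio (%d wanted)",
                      nneg, ratio, want), call. = FALSE)
    }
  }
  structure(list(positives = positives, negatives = negatives,
                 provenance = mode, seed = seed, features = features),
            class = "labelled_window_set")
}

#' @export
print.labelled_window_set <- function(x, ...) {
  cat(sprintf("<labelled_window_set> %s: %d positives, %d negatives [%s]\n",
              x$provenance, length(x$positives[[1]]),
              length(x$negatives[[1]]),
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Train a scoring model on a substrate corpus
#'
#' End-to-end per-protease training: encodes the enabled feature tracks,
#' estimates background frequencies over the complete substrate sequences,
#' builds position frequency matrices from the positive cleavage windows,
#' transforms them into scaled PSSMs, optionally fits
#' feature-position importance weights, and calibrates the decision
#' threshold on the training windows via the precision-recall sweep.
#'
#' @param substrates List of [substrate_record()]s (training split).
#' @param protease Protease name carried on the model.
#' @param feature_set `"aa_only"` (default), `"aa_physical"` or `"all"`.
#' @param weighted Fit importance weights (default `FALSE`: plain mean
#'   scoring, which the feature-contribution analysis favours).
#' @param threshold_criterion `"paper"` or `"f1"`, see
#'   [calibrate_threshold()].
#' @param negative_mode `"set2"` (default) or `"set1"`: which labelled set
#'   the threshold (and weights) are calibrated on.
#' @param seed Integer seed for sampling and weight fitting.
#' @return A [scoring_model()].
#' @export
train_scoring_model <- function(substrates, protease = "model",
                                feature_set = c("aa_only", "aa_physical", "all"),
                                weighted = FALSE,
                                threshold_criterion = c("paper", "f1"),
                                negative_mode = c("set2", "set1"),
                                seed = 0L) {
  feature_set <- match.arg(feature_set)
  threshold_criterion <- match.arg(threshold_criterion)
  negative_mode <- match.arg(negative_mode)
  feats <- feature_set_features(feature_set)
  if (!length(substrates)) {
    stop("insufficient data: empty training corpus", call. = FALSE)
  }
  labelled <- build_labelled_sets(substrates, mode = negative_mode,
                                  features = feats, seed = seed)
  # Step I: background over the complete substrate tracks
  background <- list()
  for (f in feats) {
    tracks <- vapply(substrates, function(s) encode_tracks(s, f)[[f]],
                     character(1))
    background[[f]] <- build_background(tracks, f)
  }
  # Steps II-IV: PFM and scaled PSSM per feature from positive windows
  pssms <- list()
  for (f in feats) {
    pssms[[f]] <- pfm_to_pssm(build_pfm(labelled$positives[[f]], f),
                              background[[f]])
  }
  model <- scoring_model(protease, pssms, background, threshold = 0,
                         feature_set = feature_set,
                         metadata = list(
                           n_substrates = length(substrates),
                           n_windows = length(labelled$positives[[1]]),
                           negative_mode = negative_mode,
                           threshold_criterion = threshold_criterion,
                           seed = seed,
                           version = as.character(utils::packageVersion("lysocleave"))))
  # Step VI (optional): importance weights
  if (weighted) {
    w <- fit_weights(model, labelled$positives, labelled$negatives,
                     seed = seed)
    model$weights <- w
    model$weighted <- TRUE
  }
  # Step VII: threshold from the training scores
  sc_pos <- score_window_bundles(model, labelled$positives)$final
  sc_neg <- score_window_bundles(model, labelled$negatives)$final
  model$threshold <- calibrate_threshold(
    c(sc_pos, sc_neg),
    rep(c(TRUE, FALSE), c(length(sc_pos), length(sc_neg))),
    criterion = threshold_criterion)
  model
}

#' Classification metrics from confusion counts
#'
#' @param tp,fp,tn,fn Confusion-matrix counts.
#' @return Class `lyso_metrics`: list of the counts plus `precision`,
#'   `sensitivity`, `specificity`, `f1`. Undefined ratios (zero
#'   denominators) are `NaN`, never silently 0.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  ratio <- function(num, den) if (den > 0) num / den else NaN
  precision <- ratio(tp, tp + fp)
  sensitivity <- ratio(tp, tp + fn)
  f1 <- if (is.nan(precision) || is.nan(sensitivity) ||
            precision + sensitivity == 0) {
    NaN
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = precision, sensitivity = sensitivity,
                 specificity = ratio(tn, tn + fp), f1 = f1),
            class = "lyso_metrics")
}

#' @export
print.lyso_metrics <- function(x, ...) {
  cat(sprintf(
    "<metrics> tp=%d fp=%d tn=%d fn=%d | precision=%.4f sensitivity=%.4f specificity=%.4f f1=%.4f\n",
    x$tp, x$fp, x$tn, x$fn, x$precision, x$sensitivity, x$specificity, x$f1))
  invisible(x)
}

#' Evaluate a scoring model on a labelled window set
#'
#' Scores every test window at the model's pre-fixed threshold and
#' tabulates the confusion matrix. Windows with undefined scores
#' (non-canonical characters) are excluded from the tabulation.
#'
#' @param model A [scoring_model()].
#' @param test A [build_labelled_sets()] result over (at least) the
#'   model's features.
#' @return A [classification_metrics()] object.
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(model, "scoring_model"),
            inherits(test, "labelled_window_set"))
  npos <- length(test$positives[[1]])
  nneg <- length(test$negatives[[1]])
  if (npos + nneg == 0L) stop("evaluation error: empty test set", call. = FALSE)
  sc_pos <- score_window_bundles(model, test$positives)$final
  sc_neg <- score_window_bundles(model, test$negatives)$final
  pred_pos <- sc_pos[!is.na(sc_pos)] >= model$threshold
  pred_neg <- sc_neg[!is.na(sc_neg)] >= model$threshold
  classification_metrics(tp = sum(pred_pos), fn = sum(!pred_pos),
                         fp = sum(pred_neg), tn = sum(!pred_neg))
}
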
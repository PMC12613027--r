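# Position-specific scoring matrices: background frequencies, position
# frequency matrices, log2 PSSMs with 0-1 scaling, sliding-window scoring,
# feature-importance weighting and precision-recall threshold calibration.

#' Background character frequencies of a feature track
#'
#' Counts every character over the complete encoded substrate sequences and
#' normalizes by the total residue count, yielding a probability vector
#' over the feature alphabet (characters absent from the corpus get 0).
#'
#' @param tracks Character vector of encoded track strings (whole
#'   substrates, not windows), all over the same feature alphabet.
#' @param feature Feature name, see [LYSO_FEATURES].
#' @return A named numeric vector over the full alphabet, class
#'   `background_freq`, summing to 1; attribute `feature`.
#' @export
build_background <- function(tracks, feature = "aa") {
  feature <- match.arg(feature, LYSO_FEATURES)
  alphabet <- feature_alphabet(feature)
  tracks <- tracks[nzchar(tracks)]
  if (!length(tracks)) {
    stop("insufficient data: no non-empty tracks for background frequencies",
         call. = FALSE)
  }
  cs <- unlist(strsplit(tracks, "", fixed = TRUE), use.names = FALSE)
  cs <- cs[cs %in% alphabet]          # non-canonical letters never counted
  if (!length(cs)) {
    stop("insufficient data: tracks contain no characters from the '",
         feature, "' alphabet", call. = FALSE)
  }
  counts <- table(factor(cs, levels = alphabet))
  freq <- as.numeric(counts) / length(cs)
  names(freq) <- alphabet
  structure(freq, feature = feature, class = "background_freq")
}

#' Position frequency matrix over aligned cleavage windows
#'
#' @param windows Character vector of 8-character windows (P4..P4') over a
#'   single feature alphabet.
#' @param feature Feature name.
#' @return alphabet x 8 matrix of per-position frequencies (columns sum to
#'   1), class `pfm`; attributes `feature` and `n_windows`.
#' @export
build_pfm <- function(windows, feature = "aa") {
  feature <- match.arg(feature, LYSO_FEATURES)
  alphabet <- feature_alphabet(feature)
  if (!length(windows)) {
    stop("insufficient data: no windows to build a position frequency matrix",
         call. = FALSE)
  }
  if (any(nchar(windows) != WINDOW_SIZE)) {
    bad <- which(nchar(windows) != WINDOW_SIZE)[1]
    stop(sprintf("window length error: window %d has %d characters, expected %d",
                 bad, nchar(windows[bad]), WINDOW_SIZE), call. = FALSE)
  }
  chmat <- matrix(unlist(strsplit(windows, "", fixed = TRUE),
                         use.names = FALSE),
                  ncol = WINDOW_SIZE, byrow = TRUE)
  bad <- which(!(chmat %in% alphabet))
  if (length(bad)) {
    stop(sprintf("invalid '%s' character '%s' in window %d",
                 feature, chmat[bad[1]], ((bad[1] - 1L) %% nrow(chmat)) + 1L),
         call. = FALSE)
  }
  m <- vapply(seq_len(WINDOW_SIZE), function(p) {
    as.numeric(table(factor(chmat[, p], levels = alphabet)))
  }, numeric(length(alphabet))) / length(windows)
  dimnames(m) <- list(alphabet, WINDOW_POSITIONS)
  structure(m, feature = feature, n_windows = length(windows), class = "pfm")
}

#' Transform a position frequency matrix into a scaled PSSM
#'
#' Each defined cell is the log2 enrichment of the character at that
#' position over its background frequency,
#' `raw[c, p] = log2(pfm[c, p] / bg[c])`. Cells undefined because
#' `pfm[c, p] = 0` or `bg[c] = 0` are set to the minimum over the defined
#' cells. The scaled matrix is `(raw - min) / (max - min)`, mapped into
#' `[0, 1]`; a constant raw matrix scales to all zeros.
#'
#' @param pfm A [build_pfm()] result.
#' @param bg A [build_background()] result for the same feature.
#' @return Class `feature_pssm`: list with `feature`, `raw`, `scaled`,
#'   `n_windows`.
#' @export
pfm_to_pssm <- function(pfm, bg) {
  stopifnot(inherits(pfm, "pfm"), inherits(bg, "background_freq"))
  if (!identical(attr(pfm, "feature"), attr(bg, "feature"))) {
    stop("feature mismatch between PFM and background", call. = FALSE)
  }
  P <- unclass(pfm)
  b <- as.numeric(bg)
  defined <- (P > 0) & (b > 0)       # b recycled column-wise
  if (!any(defined)) {
    stop("insufficient data: every PSSM cell is undefined", call. = FALSE)
  }
  raw <- matrix(NA_real_, nrow = nrow(P), ncol = ncol(P), dimnames = dimnames(P))
  raw[defined] <- log2((P / b)[defined])
  raw[!defined] <- min(raw[defined])
  rng <- range(raw)
  scaled <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
            else raw * 0
  structure(list(feature = attr(pfm, "feature"), raw = raw, scaled = scaled,
                 n_windows = attr(pfm, "n_windows")),
            class = "feature_pssm")
}

#' @export
print.feature_pssm <- function(x, ...) {
  cat(sprintf("<feature_pssm> feature=%s, %d windows\n", x$feature,
              x$n_windows))
  print(round(x$scaled, 3))
  invisible(x)
}

# feature sets of the three evaluation scenarios
feature_set_features <- function(feature_set) {
  switch(match.arg(feature_set, c("aa_only", "aa_physical", "all")),
    aa_only = "aa",
    aa_physical = c("aa", "charge", "hydropathy"),
    all = LYSO_FEATURES)
}

#' Assemble a scoring model
#'
#' Usually produced by [train_scoring_model()]; exposed for tests and for
#' loading externally built matrices.
#'
#' @param protease Protease (gene) name.
#' @param pssms Named list of [pfm_to_pssm()] results, one per feature.
#' @param background Named list of [build_background()] vectors.
#' @param threshold Decision threshold in `[0, 1]`.
#' @param weights Named numeric of per-(feature, position) weights summing
#'   to 1 (names `feature.position`, e.g. `aa.4`), or `NULL` for
#'   unweighted mean scoring.
#' @param feature_set One of `"aa_only"`, `"aa_physical"`, `"all"`.
#' @param metadata Free-form training metadata list.
#' @return A `scoring_model` object.
#' @export
scoring_model <- function(protease, pssms, background, threshold,
                          weights = NULL,
                          feature_set = c("aa_only", "aa_physical", "all"),
                          metadata = list()) {
  feature_set <- match.arg(feature_set)
  feats <- feature_set_features(feature_set)
  if (!setequal(names(pssms), feats)) {
    stop("feature_set '", feature_set, "' inconsistent with supplied PSSMs",
         call. = FALSE)
  }
  stopifnot(threshold >= 0, threshold <= 1)
  if (!is.null(weights)) {
    stopifnot(abs(sum(weights) - 1) < 1e-9, all(weights >= 0))
  }
  structure(list(protease = protease, pssms = pssms[feats],
                 background = background, threshold = threshold,
                 weights = weights, feature_set = feature_set,
                 weighted = !is.null(weights), metadata = metadata),
            class = "scoring_model")
}

#' @export
print.scoring_model <- function(x, ...) {
  cat(sprintf(
    "<scoring_model> %s: features [%s], %s scoring, threshold %.4f\n",
    x$protease, paste(names(x$pssms), collapse = ", "),
    if (x$weighted) "weighted" else "unweighted", x$threshold))
  invisible(x)
}

# n x 8 matrix of scaled-PSSM lookups for a vector of 8-char windows;
# rows with characters outside the alphabet come back as NA
window_lookups <- function(pssm, windows) {
  chmat <- matrix(unlist(strsplit(windows, "", fixed = TRUE),
                         use.names = FALSE),
                  ncol = WINDOW_SIZE, byrow = TRUE)
  ridx <- matrix(match(chmat, rownames(pssm$scaled)), nrow = nrow(chmat))
  out <- matrix(NA_real_, nrow = length(windows), ncol = WINDOW_SIZE)
  ok <- !is.na(ridx)
  out[ok] <- pssm$scaled[cbind(ridx[ok], col(ridx)[ok])]
  out[rowSums(!ok) > 0, ] <- NA_real_
  out
}

# Score window bundles (named list: feature -> character vector of
# windows). Returns data.frame of per-feature scores and the final score.
score_window_bundles <- function(model, bundles) {
  feats <- names(model$pssms)
  n <- length(bundles[[feats[1]]])
  per_feat <- matrix(NA_real_, nrow = n, ncol = length(feats),
                     dimnames = list(NULL, feats))
  lookups <- list()
  for (f in feats) {
    lk <- window_lookups(model$pssms[[f]], bundles[[f]])
    lookups[[f]] <- lk
    per_feat[, f] <- rowMeans(lk)
  }
  final <- if (model$weighted) {
    acc <- numeric(n)
    for (f in feats) {
      w <- model$weights[paste(f, seq_len(WINDOW_SIZE), sep = ".")]
      acc <- acc + as.numeric(lookups[[f]] %*% w)
    }
    acc
  } else {
    rowMeans(per_feat)
  }
  data.frame(per_feat, final = final, check.names = FALSE)
}

#' Score one candidate scissile bond
#'
#' Looks up the window's characters in each enabled feature's scaled PSSM.
#' Unweighted mode: the feature score is the mean of its eight lookups and
#' the final score the mean over features. Weighted mode: the final score
#' is the weight-sum over all (feature, position) lookups.
#'
#' @param model A [scoring_model()].
#' @param seq An [annotated_sequence()] with any annotation tracks the
#'   model's feature set requires.
#' @param p1 Candidate P1 index (must carry a full window).
#' @return One-row data.frame: `p1`, `window`, one column per feature,
#'   `final`, `positive`, `confidence`.
#' @export
score_site <- function(model, seq, p1) {
  w <- extract_window(seq$residues, p1)
  if (is.na(w)) {
    stop(sprintf("no full P4-P4' window at p1 = %d (sequence length %d)",
                 p1, nchar(seq$residues)), call. = FALSE)
  }
  res <- scan_sequence(model, seq)
  res[res$p1 == p1, , drop = FALSE]
}

#' Scan a sequence for cleavage sites
#'
#' Slides the 8-residue window over every candidate P1 (`4 .. L-4`) and
#' scores each with [score_site()] semantics. Windows containing
#' non-canonical residues receive `NA` scores and a negative call.
#'
#' @param model A [scoring_model()].
#' @param seq An [annotated_sequence()].
#' @return data.frame with one row per candidate P1, ascending: `p1`,
#'   `window`, per-feature scores, `final`, `positive`, `confidence`.
#' @export
scan_sequence <- function(model, seq) {
  stopifnot(inherits(model, "scoring_model"),
            inherits(seq, "annotated_sequence"))
  feats <- names(model$pssms)
  p1s <- full_window_positions(seq)
  if (!length(p1s)) {
    message("sequence '", seq$id, "' shorter than ", WINDOW_SIZE,
            " residues: no candidate sites")
    return(empty_site_scores(feats))
  }
  tracks <- encode_tracks(seq, feats)
  bundles <- lapply(tracks, windows_at, p1s = p1s)
  sc <- score_window_bundles(model, bundles)
  data.frame(p1 = p1s, window = bundles$aa, sc,
             positive = !is.na(sc$final) & sc$final >= model$threshold,
             confidence = confidence_band(sc$final, model$threshold),
             check.names = FALSE, stringsAsFactors = FALSE)
}

empty_site_scores <- function(feats) {
  df <- data.frame(p1 = integer(0), window = character(0))
  for (f in feats) df[[f]] <- numeric(0)
  df$final <- numeric(0)
  df$positive <- logical(0)
  df$confidence <- character(0)
  df
}

#' Margin-based confidence bands for site calls
#'
#' `high` when the final score clears the threshold by at least 0.1,
#' `low` below `threshold + 0.02`, else `medium`; band edges are clamped
#' to `[0, 1]`. A monotone, configurable stand-in for a per-site
#' confidence label that has no formal definition.
#'
#' @param final Numeric vector of final scores.
#' @param threshold Model threshold.
#' @param high_margin,low_margin Band margins above the threshold.
#' @return Character vector over `"low"`, `"medium"`, `"high"`.
#' @export
confidence_band <- function(final, threshold, high_margin = 0.1,
                            low_margin = 0.02) {
  hi <- min(1, threshold + high_margin)
  lo <- min(1, threshold + low_margin)
  out <- ifelse(final >= hi, "high", ifelse(final < lo, "low", "medium"))
  out[is.na(final)] <- "low"
  out
}

#' Fit per-(feature, position) importance weights
#'
#' Builds the design matrix of scaled-PSSM lookups (one column per
#' feature-position pair) for labelled positive and negative window
#' bundles, fits a bagged-tree ensemble and returns its impurity-decrease
#' importances normalized to sum to 1.
#'
#' @param model A [scoring_model()] supplying the scaled matrices.
#' @param bundles_pos,bundles_neg Named lists (feature -> character vector
#'   of 8-char windows) for the positive and negative class.
#' @param n_trees,max_depth Ensemble size and tree depth.
#' @param seed Integer seed; fitting is fully reproducible.
#' @return Named numeric vector (names `feature.position`) summing to 1.
#' @export
fit_weights <- function(model, bundles_pos, bundles_neg, n_trees = 60L,
                        max_depth = 3L, seed = 0L) {
  feats <- names(model$pssms)
  npos <- length(bundles_pos[[feats[1]]])
  nneg <- length(bundles_neg[[feats[1]]])
  if (npos == 0L || nneg == 0L) {
    stop("degenerate training: both classes must be non-empty", call. = FALSE)
  }
  X <- do.call(cbind, lapply(feats, function(f) {
    m <- rbind(window_lookups(model$pssms[[f]], bundles_pos[[f]]),
               window_lookups(model$pssms[[f]], bundles_neg[[f]]))
    colnames(m) <- paste(f, seq_len(WINDOW_SIZE), sep = ".")
    m
  }))
  y <- rep(c(1L, 0L), c(npos, nneg))
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2L) {
    stop("degenerate training: both classes must be non-empty", call. = FALSE)
  }
  imp <- gini_forest_importance(X, y, n_trees = n_trees,
                                max_depth = max_depth, seed = seed)
  if (sum(imp) <= 0) imp[] <- 1       # uninformative corpus: uniform weights
  imp / sum(imp)
}

#' Calibrate the decision threshold from labelled scores
#'
#' Sweeps candidate thresholds (the unique observed scores plus their
#' midpoints) and maximizes the selected criterion. The default,
#' `"paper"`, maximizes `precision(t) - recall(t)`, which tends towards
#' conservative (high) thresholds; `"f1"` maximizes the F1 score. Ties
#' break towards the smaller threshold.
#'
#' @param scores Numeric final scores.
#' @param labels Logical (or 0/1) true labels, same length.
#' @param criterion `"paper"` or `"f1"`.
#' @return The threshold, a value within `[min(scores), max(scores)]`.
#' @export
calibrate_threshold <- function(scores, labels, criterion = c("paper", "f1")) {
  criterion <- match.arg(criterion)
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels)) {
    stop("calibration error: both classes must be present", call. = FALSE)
  }
  u <- sort(unique(scores))
  cand <- sort(unique(c(u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  npos <- sum(labels)
  # predicted positive: score >= t
  objective <- vapply(cand, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- tp / npos
    if (criterion == "paper") {
      if (is.na(prec)) -Inf else prec - rec
    } else {
      if (is.na(prec) || prec + rec == 0) -Inf
      else 2 * prec * rec / (prec + rec)
    }
  }, numeric(1))
  cand[which.max(objective)]          # which.max takes the first (smallest t)
}
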
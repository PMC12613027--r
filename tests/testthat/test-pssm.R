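test_that("background frequencies are hand-checkable probabilities", {
  bg <- build_background("AAAA")
  expect_identical(bg[["A"]], 1)
  expect_true(all(bg[setdiff(AA_ALPHABET20, "A")] == 0))

  bg2 <- build_background(c("ACDA", "CA"))
  expect_equal(bg2[["A"]], 0.5)
  expect_equal(bg2[["C"]], 1 / 3)
  expect_equal(bg2[["D"]], 1 / 6)
  expect_equal(sum(bg2), 1, tolerance = 1e-12)

  bgc <- build_background("-+NN", feature = "charge")
  expect_equal(as.numeric(bgc[c("-", "+", "N")]), c(0.25, 0.25, 0.5))
  expect_error(build_background(character(0)), "insufficient data")
})

test_that("position frequency matrices count per-column fractions", {
  pfm <- build_pfm("TVVLFKKF")
  expect_identical(pfm["T", "P4"], 1)
  expect_identical(pfm["V", "P3"], 1)
  expect_identical(pfm["L", "P1"], 1)
  expect_identical(pfm["F", "P4'"], 1)
  expect_true(all(colSums(pfm) == 1))

  pfm2 <- build_pfm(c("AAAAAAAA", "CAAAAAAA"))
  expect_equal(pfm2["A", "P4"], 0.5)
  expect_equal(pfm2["C", "P4"], 0.5)
  expect_true(all(pfm2["A", -1] == 1))

  set.seed(3)
  wins <- replicate(30, rand_aa(8))
  expect_equal(colSums(build_pfm(wins)), setNames(rep(1, 8), colnames(pfm)),
               tolerance = 1e-12)
  expect_error(build_pfm(character(0)), "insufficient data")
  expect_error(build_pfm(c("AAAA")), "window length")
})

test_that("log2 transform, NA backfill and 0-1 scaling follow the rules", {
  # pfm == bg everywhere defined -> raw 0 -> constant -> scaled all zero
  bg <- build_background(paste(rep("ACDE", 2), collapse = ""))
  p <- pfm_to_pssm(build_pfm(c("ACDEACDE", "CDEACDEA", "DEACDEAC",
                               "EACDEACD")), bg)
  expect_true(all(abs(p$raw[c("A", "C", "D", "E"), ]) < 1e-12))
  expect_true(all(p$scaled == 0))

  # hand arithmetic: bg(A)=0.25, pfm(A,P1)=0.5 -> raw = 1
  bg2 <- build_background("ACDGACDGACDGACDG")     # A,C,D,G each 0.25
  p2 <- pfm_to_pssm(build_pfm(c("AAACAAAA", "AAAGAAAA")), bg2)
  expect_equal(p2$raw["A", "P4"], log2(1 / 0.25))
  expect_equal(p2$raw["C", "P1"], log2(0.5 / 0.25))
  # undefined cells backfilled with the matrix minimum
  expect_equal(p2$raw["D", "P1"], min(p2$raw))
  # scaling maps [min, max] onto [0, 1]
  expect_equal(min(p2$scaled), 0)
  expect_equal(max(p2$scaled), 1)
  rng <- range(p2$raw)
  expect_equal(p2$scaled, (p2$raw - rng[1]) / (rng[2] - rng[1]))
})

test_that("raw PSSMs match brute-force recomputation on micro-corpora", {
  set.seed(41)
  for (rep in 1:25) {
    n_sub <- sample(2:5, 1)
    tracks <- replicate(n_sub, rand_aa(sample(20:40, 1)))
    wins <- unlist(lapply(tracks, function(tr) {
      p1s <- sample(full_window_positions(nchar(tr)), sample(1:4, 1))
      vapply(p1s, function(p) substr(tr, p - 3, p + 4), character(1))
    }))
    p <- pfm_to_pssm(build_pfm(wins), build_background(tracks))
    expect_equal(unname(unclass(p$raw)), unname(brute_pssm_raw(wins, tracks)),
                 tolerance = 1e-12)
    expect_true(all(p$scaled >= 0 & p$scaled <= 1))
  }
})

test_that("training windows are order-invariant and P1 counts monotone", {
  set.seed(19)
  wins <- replicate(12, rand_aa(8))
  f1 <- build_pfm(wins)
  f2 <- build_pfm(sample(wins))
  expect_identical(unclass(f1), unclass(f2))
  # adding a window with character c at P1 strictly increases pfm[c, P1]
  extra <- "AAAWAAAA"
  f3 <- build_pfm(c(wins, extra))
  # counts: (k + 1) / 13 strictly exceeds k / 13 = old * 12 / 13
  expect_gt(f3["W", "P1"], f1["W", "P1"] * 12 / 13)
})

make_toy_model <- function(windows, tracks, threshold = 0.5, feats = "aa") {
  pssms <- lapply(setNames(feats, feats), function(f) {
    pfm_to_pssm(build_pfm(windows[[f]], f), build_background(tracks[[f]], f))
  })
  bgs <- lapply(setNames(feats, feats), function(f) {
    build_background(tracks[[f]], f)
  })
  fs <- if (identical(feats, "aa")) "aa_only" else
    if (setequal(feats, c("aa", "charge", "hydropathy"))) "aa_physical" else "all"
  scoring_model("toy", pssms, bgs, threshold, feature_set = fs)
}

test_that("site scores are bounded means of scaled lookups", {
  set.seed(7)
  tracks <- list(aa = replicate(3, rand_aa(30)))
  wins <- list(aa = replicate(6, rand_aa(8)))
  model <- make_toy_model(wins, tracks)
  s <- annotated_sequence("q", rand_aa(20))
  res <- scan_sequence(model, s)
  expect_identical(res$p1, 4:16)          # L - 7 = 13 candidate sites
  expect_true(all(res$final >= 0 & res$final <= 1))
  # final is the mean of the 8 P4-P4' lookups of the aa PSSM
  for (i in sample(nrow(res), 4)) {
    cs <- strsplit(res$window[i], "")[[1]]
    ridx <- match(cs, rownames(model$pssms$aa$scaled))
    expect_equal(res$final[i],
                 mean(model$pssms$aa$scaled[cbind(ridx, 1:8)]))
  }
  expect_identical(res$positive, res$final >= model$threshold)
})

test_that("scan handles short sequences and score_site targets one P1", {
  tracks <- list(aa = "ACDEFGHIKLMNPQRSTVWY")
  wins <- list(aa = c("ACDEFGHI", "CDEFGHIK"))
  model <- make_toy_model(wins, tracks)
  expect_identical(nrow(suppressMessages(
    scan_sequence(model, annotated_sequence("s", "ACDEFGH")))), 0L)
  s8 <- annotated_sequence("e", "ACDEFGHI")
  expect_identical(suppressMessages(scan_sequence(model, s8))$p1, 4L)
  one <- score_site(model, s8, 4L)
  expect_identical(nrow(one), 1L)
  expect_error(score_site(model, s8, 2L), "no full")
})

test_that("weighted scoring reduces to the weighted lookup sum", {
  set.seed(13)
  tracks <- list(aa = replicate(3, rand_aa(40)))
  wins <- list(aa = replicate(10, rand_aa(8)))
  model <- make_toy_model(wins, tracks)
  # all weight on (aa, P1): final equals the single P1 lookup
  w <- setNames(rep(0, 8), paste("aa", 1:8, sep = "."))
  w["aa.4"] <- 1
  wm <- scoring_model("toy", model$pssms, model$background, 0.5,
                      weights = w, feature_set = "aa_only")
  s <- annotated_sequence("q", rand_aa(25))
  res_u <- scan_sequence(model, s)
  res_w <- scan_sequence(wm, s)
  for (i in seq_len(nrow(res_w))) {
    p1char <- substr(res_w$window[i], 4, 4)
    expect_equal(res_w$final[i], model$pssms$aa$scaled[p1char, 4])
  }
  # uniform weights reproduce the unweighted mean
  uw <- scoring_model("toy", model$pssms, model$background, 0.5,
                      weights = setNames(rep(1 / 8, 8), names(w)),
                      feature_set = "aa_only")
  expect_equal(scan_sequence(uw, s)$final, res_u$final)
})

test_that("fit_weights concentrates importance on the informative slot", {
  set.seed(29)
  # two-feature separable fixture: classes differ only in the aa P1 residue
  consensus <- "F"; decoy <- "G"
  mk <- function(p1char, n) {
    vapply(seq_len(n), function(i) {
      w <- sample(setdiff(AA_ALPHABET20, c(consensus, decoy)), 8,
                  replace = TRUE)
      w[4] <- p1char
      paste(w, collapse = "")
    }, character(1))
  }
  pos <- mk(consensus, 120)
  neg <- mk(decoy, 120)
  tracks <- list(aa = replicate(5, rand_aa(60)))
  model <- make_toy_model(list(aa = pos), tracks)
  w <- fit_weights(model, list(aa = pos), list(aa = neg), seed = 4)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_identical(names(which.max(w)), "aa.4")
  # deterministic under a fixed seed
  w2 <- fit_weights(model, list(aa = pos), list(aa = neg), seed = 4)
  expect_identical(w, w2)
  expect_error(fit_weights(model, list(aa = pos), list(aa = character(0))),
               "degenerate")
})

test_that("threshold calibration follows its criterion and tie-breaks", {
  pos <- c(0.9, 0.92, 0.95)
  neg <- c(0.1, 0.12, 0.2)
  sc <- c(pos, neg)
  lab <- rep(c(TRUE, FALSE), each = 3)
  t_f1 <- calibrate_threshold(sc, lab, criterion = "f1")
  # any cut in (0.2, 0.9] is perfect; the smallest candidate there wins
  expect_gt(t_f1, 0.2)
  expect_lte(t_f1, 0.9)
  expect_equal(t_f1, (0.2 + 0.9) / 2)
  # printed criterion maximizes precision - recall: the most conservative
  # confusion matrix (precision 1, recall 1/3); the smaller of the tied
  # candidates achieving it is the 0.92/0.95 midpoint
  t_p <- calibrate_threshold(sc, lab, criterion = "paper")
  expect_equal(t_p, (0.92 + 0.95) / 2)
  pred <- sc >= t_p
  expect_identical(sum(pred & lab), 1L)
  expect_identical(sum(pred & !lab), 0L)
  expect_true(t_p >= min(sc) && t_p <= max(sc))
  expect_error(calibrate_threshold(c(0.5, 0.6), c(TRUE, TRUE)), "calibration")
})

test_that("confidence bands are monotone in the final score", {
  expect_identical(confidence_band(c(0.1, 0.52, 0.7), 0.5),
                   c("low", "medium", "high"))
  expect_identical(confidence_band(NA_real_, 0.5), "low")
})
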
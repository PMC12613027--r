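test_that("complete digestion partitions the sequence", {
  fr <- complete_fragments("PEPTIDE", 3)
  expect_identical(fr$sequence, c("PEP", "TIDE"))
  expect_identical(complete_fragments("PEPTIDE")$sequence, "PEPTIDE")
  fr2 <- complete_fragments("PEPTIDE", c(2, 5))
  expect_identical(fr2$sequence, c("PE", "PTI", "DE"))
  expect_identical(paste(fr2$sequence, collapse = ""), "PEPTIDE")
  expect_error(complete_fragments("PEPTIDE", 7), "out of range")
  expect_warning(complete_fragments("PEPTIDE", c(3, 3)), "duplicate")
})

test_that("partial digestion enumerates contiguous segment runs", {
  pf <- partial_fragments("PEPTIDE", 3)
  expect_setequal(pf$sequence, c("PEP", "TIDE", "PEPTIDE"))
  expect_identical(nrow(partial_fragments("PEPTIDE")), 1L)
  pf2 <- partial_fragments("ACDEFGHIKL", c(3, 7))   # n = 2 -> 6 fragments
  expect_identical(nrow(pf2), 6L)
  expect_true("ACDEFGHIKL" %in% pf2$sequence)
})

test_that("counting laws hold for up to 12 cuts against enumeration", {
  set.seed(31)
  for (n in 0:12) {
    L <- 40L
    s <- rand_aa(L)
    cuts <- sort(sample(1:(L - 1), n))
    cf <- complete_fragments(s, cuts)
    expect_identical(nrow(cf), n + 1L)
    expect_identical(paste(cf$sequence, collapse = ""), s)
    pf <- partial_fragments(s, cuts)
    expect_identical(nrow(pf), ((n + 1L) * (n + 2L)) %/% 2L)
    # brute enumeration of contiguous runs of complete segments
    bounds <- rbind(c(1, cuts + 1), c(cuts, L))
    runs <- list()
    for (i in 1:(n + 1)) for (j in i:(n + 1)) {
      runs[[length(runs) + 1]] <- c(bounds[1, i], bounds[2, j])
    }
    got <- mapply(function(a, b) paste(a, b), pf$start, pf$end)
    want <- vapply(runs, function(r) paste(r[1], r[2]), character(1))
    expect_setequal(got, want)
  }
})

test_that("sequential digestion loses sites straddling earlier cuts", {
  pA <- parse_pattern("x/x/x/R|x/x/x/x", "protA")
  pB <- parse_pattern("x/x/x/D|E/x/x/x", "protB")
  # protA cuts at p1 = 5; protB's only site (p1 = 8) has a window spanning
  # residues 5..12, which straddles protA's cut and is lost
  s <- annotated_sequence("fix", "AAAARGGDEGGGAAAA")
  expect_identical(match_pattern(pB, s)$p1, 8L)
  out <- sequential_digest(s, digest_plan(list(pA, pB), min_length = 1))
  expect_identical(out$start, c(1L, 6L))
  expect_identical(out$end, c(5L, 16L))
  # reversed order lets protB act first: order changes the output
  out_rev <- sequential_digest(s, digest_plan(list(pB, pA), min_length = 1))
  expect_false(identical(out$sequence, out_rev$sequence))
  expect_identical(out_rev$start, c(1L, 9L))
})

test_that("sequential output tiles the input and the length filter bites", {
  pA <- parse_pattern("x/x/x/R|x/x/x/x", "protA")
  set.seed(47)
  s <- annotated_sequence("t", rand_aa(120))
  all_fr <- sequential_digest(s, digest_plan(list(pA), min_length = 1))
  expect_identical(paste(all_fr$sequence, collapse = ""), s$residues)
  expect_identical(all_fr$start[-1], all_fr$end[-nrow(all_fr)] + 1L)
  # identical to single complete digestion at the matched sites
  cuts <- match_pattern(pA, s)$p1
  expect_identical(all_fr$sequence, complete_fragments(s, cuts)$sequence)
  # min_length filter removes only the short fragments
  filt <- sequential_digest(s, digest_plan(list(pA), min_length = 10))
  expect_setequal(filt$sequence,
                  all_fr$sequence[nchar(all_fr$sequence) >= 10])
})

test_that("re-applying a protease adds no new cuts", {
  pA <- parse_pattern("x/x/x/R|x/x/x/x", "protA")
  set.seed(53)
  for (i in 1:5) {
    s <- annotated_sequence("t", rand_aa(80))
    once <- sequential_digest(s, digest_plan(list(pA), min_length = 1))
    twice <- sequential_digest(s, digest_plan(list(pA, pA), min_length = 1))
    expect_identical(once$sequence, twice$sequence)
  }
})

test_that("fragment scores average the producing boundary sites", {
  # model protease with a fixed threshold so some sites score positive
  tracks <- list(aa = "RRRRRRRRGGGGGGGG")
  model <- scoring_model(
    "m", list(aa = pfm_to_pssm(build_pfm(c("GGGRRGGG", "GGGRAGGG")),
                               build_background(tracks$aa))),
    list(aa = build_background(tracks$aa)), threshold = 0,
    feature_set = "aa_only")
  s <- annotated_sequence("sc", "AAAAAAAAAAAAAAAA")
  out <- sequential_digest(s, digest_plan(list(model), min_length = 1))
  for (i in seq_len(nrow(out))) {
    st <- out$steps[[i]]
    if (is.null(st)) {
      expect_true(is.na(out$score[i]))
    } else {
      expect_equal(out$score[i], mean(st$score))
    }
  }
})

test_that("molecular weights are additive residue sums plus water", {
  expect_equal(peptide_mw("G"), 75.07, tolerance = 1e-3)
  expect_error(peptide_mw(""), "empty")
  expect_error(peptide_mw("GBX"), "invalid")
  set.seed(61)
  for (i in 1:5) {
    a <- rand_aa(sample(3:12, 1)); b <- rand_aa(sample(3:12, 1))
    expect_equal(peptide_mw(paste0(a, b)),
                 peptide_mw(a) + peptide_mw(b) - 18.01524,
                 tolerance = 1e-9)
    expect_lt(peptide_mw(a, monoisotopic = TRUE), peptide_mw(a))
  }
})

test_that("isoelectric points zero the charge curve", {
  set.seed(67)
  for (i in 1:6) {
    s <- rand_aa(sample(5:20, 1))
    pi <- peptide_pi(s)
    expect_lt(abs(peptide_charge(s, pi)), abs(peptide_charge(s, pi + 0.2)))
    expect_gt(peptide_charge(s, pi - 0.1), peptide_charge(s, pi + 0.1))
  }
  expect_gt(peptide_pi("KKKK"), peptide_pi("DDDD"))
  # charge at the returned pI is near zero
  expect_lt(abs(peptide_charge("ACDEFGHIKL", peptide_pi("ACDEFGHIKL"))), 0.05)
})
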
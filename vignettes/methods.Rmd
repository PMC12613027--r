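---
title: "Scoring-matrix cleavage prediction and digestion simulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring-matrix cleavage prediction and digestion simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysocleave)
```

## The model

A protease cleavage site is represented by the eight residues flanking
the scissile bond, P4‑P3‑P2‑P1 | P1′‑P2′‑P3′‑P4′, with P1 the 1-based
index of the residue N-terminal to the bond. Scoring is defined only on
complete windows — positions with `p1 < 4` or `p1 > L − 4` are never
scored and no padding is used — so a length-`L` sequence carries exactly
`max(0, L − 7)` candidate sites.

For data-rich proteases, the model is a bundle of per-feature scoring
matrices over five parallel character tracks: amino-acid identity,
side-chain charge, hydropathy, secondary structure and discretized
solvent accessibility. The structural tracks are *consumed* as input
(computed by an external structure predictor); this package never
computes them. Training proceeds in the canonical steps:

1. **Background** `F[c]`: frequency of each encoded character over the
   complete training-substrate tracks, normalized by total residue
   count. The matching print formula divides by the number of substrates
   instead, which does not yield probabilities; we normalize so that the
   next step is a proper likelihood ratio (this is the package's one
   deliberate deviation from the printed arithmetic, together with the
   scaling in step 3).
2. **Position frequency matrix** `PFM[c, p]`: fraction of training
   windows with character `c` at window position `p`; columns sum to 1.
3. **Scoring matrix**: `raw[c, p] = log2(PFM[c, p] / F[c])` where both
   terms are positive; undefined cells (zero numerator or background)
   are backfilled with the minimum over the defined cells. The scaled
   matrix is `(raw − min) / (max − min)`, guaranteeing entries in
   [0, 1]; the printed variant divides by the un-shifted maximum, which
   can exceed 1 and can be negative, violating the stated 0–1 contract.
   A constant raw matrix (no information) scales to all zeros rather
   than 0/0.
4. **Scoring**: a site's per-feature score is the mean of the eight
   scaled lookups of its window; the final score is the mean over
   enabled features (`aa_only`, `aa_physical` = + charge/hydropathy, or
   `all`). No pseudocounts are used anywhere: zero cells flow through
   the backfill rule above, which is the faithful behaviour for this
   family of models.

### Feature weighting

Plain averaging treats all 8 positions (and all features) equally. The
optional weighted mode replaces the mean with a weighted sum over all
(feature, position) pairs, with weights taken from the normalized
impurity-decrease importances of a bagged classification-tree ensemble
fit on the scaled lookups of labelled windows. No random-forest package
is available in the supported dependency set, so the estimator — bagged
depth-limited CART with Gini importance, `mtry = ceiling(sqrt(p))` — is
implemented in `R/forest.R`; it is seeded and fully reproducible. On
separable fixtures the importance mass concentrates on the informative
coordinate, which is all the weighting step requires. Unweighted scoring
remains the default: in the reference analysis the weighted variant
improved sensitivity but did not beat the amino-acid-only model overall,
and the same pattern holds on synthetic corpora here.

### Threshold calibration

The decision threshold is swept over the unique observed training scores
plus their midpoints (a finite grid that realizes every achievable
confusion matrix). Two criteria are provided:

- `paper` (default): `T = argmax_t (precision(t) − recall(t))`, as
  printed in the source method. This objective is maximized by
  conservative cuts — precision 1 at minimal recall when classes
  separate — and tends toward the top of the score range.
- `f1`: maximize F1, the conventional reading of "optimal
  precision–recall trade-off". This is what the synthetic-recovery
  tests use, since the `paper` criterion by construction sacrifices
  recall.

Ties break toward the smaller threshold. Note one corner the contract
leaves open: when a midpoint and an observed score realize the same
confusion matrix, the tie-break picks the midpoint (the smaller
candidate); tests therefore assert the resulting confusion matrix, not
the literal cut value. The choice of criterion is surfaced in the CLI
(`--criterion`).

### Confidence labels

Per-site confidence has no formal definition in the source description,
so a monotone margin band is used: `high` if the final score clears the
threshold by ≥ 0.1, `low` below threshold + 0.02, else `medium`
(clamped to [0, 1]; both margins are arguments of
`confidence_band()`). Pattern matches, being exact, report `high`.

## Consensus patterns

Proteases with too few known substrates for matrix training use
consensus patterns over the same eight positions: `x` wildcard, residue
runs as allowed-sets, and exclusions written `x[^RK]` or
`x(not R or K)`. Exclusions are kept explicit (not complemented into
allowed-sets) so the canonical printed form round-trips against the
published table. A stray `=` is accepted as a synonym for the
scissile-bond marker `|` because the source text prints one pattern that
way. Multi-letter tokens always bind a single position (e.g. `ND` is the
allowed-set {N, D}, never a dipeptide). The packaged registry maps each
of the 17 endoproteases to exactly one mechanism — pattern or matrix —
and refuses registries that violate this.

## Digestion semantics

- **Complete**: `n` cut positions partition the sequence into `n + 1`
  fragments whose concatenation restores the input.
- **Partial**: every contiguous run of complete-digest segments, i.e.
  `(n+1)(n+2)/2` fragments including the full-length sequence. This is
  a whole-sequence enumeration mode, deliberately *not* mixed into the
  sequential simulation: the two model different experimental
  narratives (incomplete digestion vs ordered protease action).
- **Sequential**: protease `k` acts independently on every fragment
  left by protease `k − 1`, seeing only windows fully contained in the
  fragment. A site whose window straddles an earlier cut therefore no
  longer exists — the central behaviour the fixture tests assert. Within
  one step all called sites are applied simultaneously. The
  minimum-length filter (default 4 residues, roughly the smallest
  epitope-like peptide; a CLI flag) applies to the final output only:
  short intermediates stay in the pool because a later protease's
  relevant context may span them, and sub-window intermediates are
  unscoreable anyway. Windows near the fresh termini of intermediate
  fragments are undefined by the full-window rule, applied uniformly;
  whether a biological protease could attack those termini is not
  modelled.

A fragment's `score` is the mean final score of the scored sites that
produced its two boundaries (terminal boundaries and pattern matches
contribute nothing; fragments with no scored boundary have `NA`). This
is an artifact-level convention — the source output format requires an
"assigned score" without defining one.

Peptide masses are additive residue masses plus one water (average by
default, monoisotopic by flag). Isoelectric points are the bisection
root of the Henderson–Hasselbalch net-charge curve over an EMBOSS-style
pKa table; the table is an argument, not a constant, because published
pKa sets differ and the source does not specify one.

## Training protocol

Redundancy is removed by greedy longest-first clustering at 70 %
identity, where identity is exact matches in a global alignment (match
1 / mismatch 0 / gap −1, via Biostrings) divided by the shorter
sequence length — a desk-scale stand-in for the conventional clustering
tool, oracle-tested against brute-force all-pairs clustering. Splits
are at substrate level (90/10, floor with a minimum of one test
substrate), so no window of a test substrate leaks into training.
Labelled sets come in two flavours: `set1` keeps every non-annotated
full-window position as a negative (the realistic, heavily imbalanced
regime — including near-miss windows within 3 residues of a true site,
on which the source is silent); `set2` down-samples negatives to 3:1
without replacement, seeded. Metrics leave undefined ratios as `NaN`,
never silent zeros. Thresholds are calibrated on the training windows
of the same labelled-set mode as evaluation by default (`set2` for
training calibration), configurable per run.

## The synthetic world

`generate_corpus()` draws sequences i.i.d. from a uniform residue
background (uniform keeps every matrix oracle hand-checkable; a
composition-weighted background can be passed instead) and overwrites
planted 8-residue windows with draws from a motif: one categorical
distribution per position plus a structural bias (favoured
secondary-structure class, solvent-accessibility range) and a site
density in sites per 100 residues (default 2, Poisson-distributed with
at least one site per substrate). Planted windows never overlap and sit
at least four residues from the termini, so every recorded site is
scoreable and labels are unambiguous.

The default motif mirrors the reported specificity of cathepsin D: P1
carries a 0.6 point mass on F with L (0.20) and W (0.12) as runners-up,
P2 is enriched for C and acidic residues, P1′ for I/F, and sites are
planted in beta-strand, low-accessibility context. These values were
fixed before any acceptance measurement and are not tuned.

What the generator does *not* emulate: real substrate length and domain
structure, residue composition, correlated positions within motifs,
homology structure between substrates (each synthetic substrate is
independent), or annotation noise in structural tracks. A green
recovery test therefore establishes that the implementation learns what
was planted — it says nothing about absolute accuracy on real
substrates, which is why the realistic performance numbers of the
source analysis are out of scope here.

## Numerical and degenerate-input choices

- Bisection for pI converges to 0.01 pH; net charge is strictly
  monotone in pH, so the root is unique.
- Sequences shorter than 8 residues scan to an empty site list (logged),
  not an error; digestion of such sequences yields the identity
  fragment.
- Non-canonical residues (B, J, O, U, X, Z) are rejected by default; a
  permissive flag admits them, in which case any window containing one
  is skipped (scored `NA`, never positive) — the matrices have no
  column for them.
- Duplicate cut positions collapse with a warning; out-of-range cuts
  are errors.
- All stochastic steps (splitting, under-sampling, weight fitting,
  corpus generation) take explicit integer seeds, restore the caller's
  RNG state, and default to 0.

## Known limitations

- Exopeptidases are out of scope by design; only endoprotease
  mechanisms are registered.
- Feature independence is assumed (five separate matrices); coupled or
  dipeptide features are not modelled.
- Protease abundance/kinetics and pH-dependent specificity (relevant
  for legumain in acidic compartments) are not modelled; the sequential
  cutter's protease *order* is the only abundance proxy.
- The registry transcribes the published tool-configuration column
  verbatim, including rows that arguably conflict with the narrative
  protease descriptions (see the package sources for the affected
  entries); users can edit the packaged TSV.
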
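---
title: "Methods: window encodings, F-score ranking and the exact-solve RBF network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window encodings, F-score ranking and the exact-solve RBF network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubilys)
```

## The problem and the model

Ubiquitylation is the covalent attachment of ubiquitin to a substrate
lysine, carried out by the E1 (activating), E2 (conjugating) and E3
(ligating) enzyme cascade. Because the E3 ligase contacts its substrate over
an extended interface, the sequence determinants of a ubiquitylated lysine
need not sit immediately beside it; discriminative residues can occur many
positions away. `ubilys` treats site prediction as binary classification of
candidate lysines, each represented by a `2n+1`-residue window (offsets
−n…+n; default n = 20, a 41-mer) so that such distant determinants are
inside the representation.

The classifier is a radial basis function network in its classical
exact-solve form. Every training instance is a hidden unit with a Gaussian
activation; with shared bandwidth $\sigma$ the output node for class $j$ is

$$y_j(x) = \sum_{i=1}^{k} w_{ji}\, \exp\!\left(-\frac{\lVert x - m_i
\rVert^2}{2\sigma^2}\right), \qquad k = n_{\text{train}},$$

and the output weights solve the regularised linear system
$(\Phi + \lambda I)W = Y$, where $\Phi_{ab} = \varphi(\lVert x_a - x_b
\rVert)$ and $Y$ holds one-hot class indicators. On pairwise-distinct
points the Gaussian kernel matrix is symmetric positive definite, so at
$\lambda = 0$ the network interpolates its training targets exactly — a
property the test suite asserts to $10^{-6}$ after the floating-point
solve. Prediction takes the arg-max output node; exact ties go to the
class that sorts first (`negative` under canonical labels), and a
threshold mode (`positive` iff $y_+ - y_- \ge t$) exposes the
sensitivity/specificity trade-off.

Assumptions worth keeping in mind: the model has no notion of sequence
beyond the window; the all-centers design means model complexity grows with
the training set, so on weakly informative features it behaves like a
high-variance nearest-neighbour-style rule; and class imbalance is not
corrected — an unweighted fit on site data (typically one positive per
tens of negative lysines) favours specificity over sensitivity.

## Feature encodings

All encoders share the fixed residue order `ARNDCQEGHILKMFPSTWYV` and are
pure functions; window positions beyond the protein termini are carried as
the marker `-`.

* **AAC** (20-D) and **AAPC** (400-D): occurrence counts of residues and of
  adjacent residue pairs, both divided by the number of *effective*
  residues in the window. Terminal markers and the unknown residue `X`
  contribute to neither numerator nor denominator; pairs spanning a marker
  are skipped (so a marker-free window of L residues has AAPC sum
  `(L−1)/L` — kept deliberately, since the residue-count denominator is the
  conventional one for pair composition).
* **BLOSUM** (21·(2n+1)-D): each position contributes the BLOSUM62 row of
  its residue rescaled to [0, 1] by the global matrix minimum and maximum —
  global rather than per-row scaling is the simplest order-preserving map —
  plus a 21st terminal channel that is 1 exactly when the position is
  outside the protein.
* **PSSM400** (400-D): the `m` PSSM rows centered on the site (m odd,
  default `2n+1`) are summed by the residue *type* of each row into a
  20×20 matrix, every element is divided by `m`, squashed with the
  logistic function `1/(1+exp(−x))`, and flattened row-major. Rows falling
  outside the protein are skipped but the divisor stays `m`, keeping the
  scale of truncated windows comparable. A residue type absent from the
  window leaves its row at `logistic(0) = 0.5`. The logistic is the
  standard squash for PSSM-derived features and keeps every output in
  (0, 1).
* **ASA** ((2n+1)-D): percent solvent accessibility divided by 100;
  out-of-range positions are 0.
* **SS** (3·(2n+1)-D): one-hot helix/sheet/coil per position
  (`H → 100`, `E → 010`, `C → 001`); out-of-range positions are all-zero.

Blocks are concatenated in the fixed order AAC, AAPC, BLOSUM, PSSM400,
ASA, SS, and the assembled vector records a block layout table. Composition
blocks are computed over the window rather than the whole protein (a
window-level analysis is what makes the positional experiments coherent);
`encode_aac()` on a full sequence provides the protein-level variant when
wanted.

## F-score ranking and positional scans

The F-score of feature *i* is the ratio of the squared deviations of the two
class means from the grand mean to the sum of the two within-class sample
variances (n−1 denominators). It is affine-invariant and symmetric under
label swap; a zero numerator yields 0, and perfect zero-variance separation
yields the `Inf` sentinel, which preserves ordering and serialises cleanly.
Both properties and exact agreement with an explicit-sum evaluation are
asserted over random draws in the tests.

`positional_scan()` converts the window into per-offset scores: at each
offset the `composition` channel builds 20 residue-identity indicators
(offset 0 is excluded — the center is always K) and the `pssm` channel takes
the 20 profile scores of the residue at that offset; the 20 per-channel
F-scores are aggregated by sum (default) or max. Sum was preferred as the
smoother aggregate; both are exposed. No significance threshold is imposed —
the scan reports raw aggregates and leaves calibration to permutation, as in
the shuffle test. Note that profile-derived channels smear signal over the
profile's local window (±3 in the generator), so neighbours of a planted
offset also score highly; tests assert proximity, not exact rank.

## Redundancy reduction

Two proteins are homologous when their best local alignment (BLOSUM62, gap
open 11, extend 1 — standard protein pairwise defaults) has identity above
0.30, identity being matches over alignment length. Identity is computed on
a canonical ordering of each pair, making it symmetric even when equal-score
optimal alignments differ. Among homologous proteins, fragments with
character-identical windows and the same class label collapse to the first
occurrence in input order (determinism); positive and negative sets are
reduced independently; chains are handled pairwise, not by clustering. A
protein counts as homologous to itself, so identical windows at different
sites of one protein also collapse — the degenerate case of 100% identity.
"Same site" is interpreted as identical window strings rather than equal
absolute coordinates, since coordinates differ between homologs. The
reduction is idempotent, monotone in the threshold, and never alters labels,
all of which are asserted against a brute-force oracle.

## Cross-validation harnesses

Folds are stratified by class at the site level with the partition seed
recorded in the result (per-stratum fold sizes differ by at most one);
optional protein-level grouping keeps all sites of a protein in one fold to
prevent homolog leakage. Metrics are pooled (micro-averaged) over folds —
the k rounds are combined into a single confusion table — and undefined
ratios are reported as `NA`, never 0. `window_sweep()` and
`feature_comparison()` rerun the whole encode-train-test cycle per window
length or block combination under a shared partition seed so rows are
comparable.

## The synthetic proteome generator

The generator is the package's study-condition definition, not a tuning
knob. Defaults, fixed once: uniform 1/20 background composition (neutral;
a realistic frequency table can be supplied), protein lengths 200–400
(typical database range at small scale), positive rate 0.2 among lysines
(a 1:4 site imbalance — severe enough to matter, mild enough for desk-scale
training sets), enrichment of D/E — the acidic residues that dominate real
site neighbourhoods — with probability 0.8 at offsets
{−16, −10, −3, −1, +1, +5, +13, +17}, i.e. positions both near and far from
the site, matching the positional structure the method is designed to
detect; a 10-percentage-point mean ASA elevation and a 0.5 coil/helix
rewrite probability at offsets ±5 of positive sites (modified lysines
prefer exposed, coil/helix regions); and unit-sd integer-rounded noise on
synthetic PSSMs. PSSMs are pseudo-count log-odds of the emitted sequence's
±3 local composition — no alignment database is consulted, but the property
the PSSM400 encoder exploits (profiles correlate with local composition) is
preserved. Generation is fully deterministic given the seed, emits exactly
the file formats the readers accept, and the truth record retains every
planted effect.

What the generator does **not** emulate: evolutionary conservation
structure in profiles (phylogeny, domain architecture), compositional
heterogeneity across proteins, genuine E3-motif biophysics, and homology
families (sequences are independent draws). Passing tests therefore show
that the machinery recovers the *kind* of structure it models — planted
positional enrichment, profile elevation, structural bias — not that it
attains any particular accuracy on real proteomes.

## Numerical choices

* **Ridge default `1e-8`.** The exact solve is singular when duplicate
  feature rows occur (likely after composition encoding of short windows);
  the tiny ridge guarantees solvability while leaving interpolation
  behaviour intact. `ridge = 0` requests the exact solve and errors
  informatively on duplicates. Increasing the ridge never increases the
  weight Frobenius norm (asserted).
* **Kernel convention** `exp(−d²/(2σ²))` with σ = 5 by default; a
  `bandwidth_convention` switch provides `exp(−d²/σ²)` for parity with
  implementations that fold the 2 into the bandwidth.
* **Model files** are JSON with doubles serialised as `%.17g` strings —
  17 significant digits reproduce an IEEE double exactly, so save → load →
  predict is bit-identical (asserted over random models).
* **Degenerate inputs** error early and by name: all-marker windows,
  profile/sequence length mismatches, out-of-range ASA, non-K site
  positions, single-class training data, sub-k class sizes under
  stratification.

## Choice of encoding in the window-length experiment

A point that surfaced while designing the window-sweep harness: with
window-level *composition* features, distant signal planted at a handful of
offsets is diluted by averaging over the window — four enriched offsets
among 41 shift the D/E fraction by well under two within-class standard
deviations, even though a rule reading those offsets directly would be
almost perfect. The positional BLOSUM encoding has no such dilution: the
11-mer physically lacks the distant offsets and the 41-mer contains them,
so the accuracy contrast between windows cleanly measures the value of
distant sequence information. The packaged experiment
(`window_sweep(blocks = "BLOSUM")`) and the acceptance script use the
positional encoding for that contrast, with the near-signal control
(enrichment confined to ±2) expected flat; the composition-based sweep
remains available and shows the same trend, attenuated by dilution.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen to keep a
laptop run comfortable: simulated pools of 50–150 proteins of 200–400
residues; site sets of 300 positives / 1,200 negatives (positional-scan and
sweep experiments) or 500/500 (null calibration); 1,000 random draws for the
statistic-level oracle checks; 200 points in 20 dimensions for the
interpolation check; ten generator seeds for the recovery experiment.

## Known limitations

* The homology gate uses local-alignment identity; global-identity
  reduction and CD-HIT-style clustering are out of scope.
* No imbalance correction (resampling or cost weighting) is applied; the
  threshold mode is the only sensitivity lever.
* The all-centers solve is O(n³) in training-set size; the optional seeded
  center subsampling trades fidelity for scale but is off by default.
* Physicochemical-property and reduced-alphabet encodings are not
  implemented.
* Real-proteome performance depends on profile quality (PSI-BLAST
  database, ASA/SS predictors), which the package consumes but does not
  produce.
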
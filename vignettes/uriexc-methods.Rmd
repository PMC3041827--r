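---
title: "Predicting urine excretory proteins from sequence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting urine excretory proteins from sequence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uriexc)
```

## The problem

Proteins reach urine by two filters in series: secretion from cells into the
bloodstream, then passage through the glomerular membrane of the kidney. Both
steps leave footprints in the amino-acid sequence — secreted proteins carry
signal peptides; the glomerular wall is negatively charged, so positively or
neutrally charged proteins pass more readily; and urinary proteins are
enriched for particular secondary-structure content. `uriexc` turns these
footprints into a classifier: given a protein sequence, predict whether the
protein can be excreted into urine. Combined with a list of genes
differentially expressed in diseased versus control tissue, the classifier
nominates candidate urinary biomarkers that can then be tested by targeted,
antibody-based assays instead of blind comparative proteomics.

## Feature model

Each sequence maps to a fixed, ordered vector of **243 feature values**
(`default_registry()`), grouped as:

| block | values | what it measures |
|---|---|---|
| amino-acid composition | 20 | residue fractions |
| CTD descriptors | 147 | composition/transition/distribution under 7 three-group physicochemical partitions |
| secondary structure | 3 | helix/strand/coil content estimate (Chou–Fasman propensities) |
| disorder | 3 | fold-index score, disordered fraction, longest disordered run |
| signal peptide | 2 | h-region window score, binary call |
| membrane/motifs | 3 | transmembrane-window count, beta-barrel contrast, twin-arginine motif |
| glycosylation | 2 | N-sequon density, S/T density |
| charge | 7 | Henderson–Hasselbalch net charge, per-class fractions |
| ProtParam indices | 5 | MW, pI, GRAVY, instability, aliphatic index |
| sequence statistics | 51 | N-/C-terminal window compositions, length, global fractions |

Two design facts deserve emphasis. First, the original feature set was
computed with external prediction servers; this package replaces them with
deterministic, desk-scale approximations built on shipped, versioned
coefficient tables (Kyte–Doolittle hydropathy, the EMBOSS pKa set, average
residue masses, Chou–Fasman propensities, the Guruprasad dipeptide
instability weights, Dubchak-style CTD partitions). The registry records that
these are approximations: a green test establishes that *this package's*
features behave as documented, not that they reproduce any server's output.
Second, the per-group dimensional breakdown summing to 243 is not published;
the breakdown above is this package's convention, and the registry is
data-driven so other breakdowns remain configurable.

Nonstandard residues (B, J, Z, U, O) are mapped to `X` and excluded from
composition denominators — real database entries are accepted without
silently distorting fractions. Sliding windows shrink symmetrically at
sequence ends rather than padding with fabricated residues.

## Feature selection: the F-score

For feature $i$ with $n_+$ positive and $n_-$ negative training values,

$$F_i \;=\; \frac{(\bar x_i^{+}-\bar x_i)^2 + (\bar x_i^{-}-\bar x_i)^2}
{\frac{1}{n_+-1}\sum_k (x^{+}_{k,i}-\bar x_i^{+})^2
 + \frac{1}{n_--1}\sum_k (x^{-}_{k,i}-\bar x_i^{-})^2},$$

where $\bar x_i$ is the pooled mean (the source text does not say whether the
overall mean is pooled or a midpoint of class means; pooled is the standard
reading and is used here). Features with $F$-score **at or above** a
threshold are kept. Two edge policies are ours: a zero denominator yields 0
when the class means agree and $+\infty$ when they differ, so a perfectly
separating feature can never be discarded; rank ties break by ascending
registry index for determinism.

## Classifier and training procedure

The classifier is a soft-margin SVM with RBF kernel
$K(x,y)=\exp(-\gamma\lVert x-y\rVert^2)$. No SVM library is assumed: the
dual is solved by an in-package SMO implementation (maximal-violating-pair
working-set selection, duality-gap tolerance $10^{-3}$), exposed as
`rbf_svm_fit()`.

Training (`select_threshold_and_train()`) follows the published recipe: for
each candidate F-score threshold, filter features, then repeat five times a
random stratified half-split, a grid search over $(C,\gamma)$ on the
sub-training half and an error measurement on the sub-validation half; pick
the threshold with the lowest average validation error; retrain on all data
with the winning feature set. Points the source leaves open, fixed here as
package conventions:

* **Scaling** — min–max to $[0,1]$, fitted on (sub-)training rows only
  (configurable: z-score, none).
* **Threshold candidates** — empirical quantiles $0,0.1,\dots,0.9$ of the
  observed finite F-scores, adapting to any dataset.
* **Grids** — the canonical log-scale grids $C\in 2^{-5..15}$,
  $\gamma\in 2^{-15..3}$ (step 2).
* **Ties** — thresholds tie toward the smaller value (more features); grid
  points toward smaller $C$, then smaller $\gamma$.
* **Final $(C,\gamma)$** — whether the published final parameters came from
  the sub-splits or a final search is not stated; here one more round of
  repeated-split grid search is run on the full data with the winning
  feature set, and the pair with the lowest mean validation error wins.
* **Imbalance** — no reweighting by default (matching the source's silence
  on its 1:2 imbalance); a class-weight option is exposed.

Everything is deterministic given `(data, config, seed)`: each
(threshold, repeat) cell of the validation-error table derives its own split
seed from the master seed, and the tests recompute single cells bit-exactly.

## Negative-set sampling

Negatives are drawn only from protein families containing no positive
protein — a protein belonging to *any* positive-containing family is
excluded entirely. "At least one per family, proportional to family size" is
realized by largest-remainder rounding with an at-least-one floor, capped at
family size; multi-family proteins are pooled once under their largest
eligible family. The allocation is fully deterministic; the seed only picks
the members within each family. A budget below the number of eligible
families is rejected as unsatisfiable rather than silently violating the
one-per-family rule.

## Paired differential expression

For gene $g$ over $n$ tumor/control tissue pairs, $K_{exp}$ counts pairs
whose fold-change reaches the cutoff (default 2); the default direction is
"either", i.e. the larger of the two ratios. Significance uses a
within-pair label-swap permutation null: under no effect, tumor and control
are exchangeable within a pair, so swapping with probability ½ generates the
exact null. One subtlety is ours: the "either"-direction $K_{exp}$ is
*invariant* under swaps (swapping inverts a ratio but not its magnitude), so
the two-sided permutation statistic is $\max(K_{up}, K_{down})$ — the larger
directional count — which is swap-variant and exact under exchangeability.
Only exceeding pairs can change direction under a swap, so the null collapses
to a binomial orbit; the Monte Carlo permutation (default) and the
closed-form binomial option (`exact = TRUE`) agree.

Because the statistic is integer-valued, the test is **conservative**: at a
nominal 0.05 the measured type-I error on exchangeable nulls (1,000 genes ×
80 pairs, lognormal noise) is about 0.034. That is the price of an exact
discrete test, and it sits within the ±0.02 calibration band the acceptance
suite checks. No multiple-testing correction is applied by default, matching
the plain $p<0.05$ rule; a Benjamini–Hochberg flag is available.

## The synthetic world

No training accessions are published, so the generators state a world and the
tests live in it:

* **Proteins** (`simulate_proteins()`): 200 positives / 400 negatives (the
  1:2 imbalance of the real design), lengths 100–500. Positives carry a
  signal-peptide-like prefix (Met + basic n-region + 9–12-residue
  hydrophobic h-region + small-residue c-region) with probability 0.9 —
  most secreted proteins have one — and are K/R- and helix-residue-enriched
  (+50 % and +30 % relative frequency), mirroring the charge and
  helix-content signals reported as top discriminators. Negatives are drawn
  from average human-proteome composition.
* **Families** (`simulate_family_table()`): 30 families of 2–20 proteins,
  30 % contaminated with positives.
* **Expression** (`simulate_paired_expression()`): 1,000 genes × 80 pairs,
  lognormal baselines (sdlog 1 around 100), per-measurement lognormal noise
  sdlog 0.5 (≈ 65 % CV on the tumor/control ratio, a realistic microarray
  regime), 5 % planted genes shifted 4-fold in half of the pairs.

What this world does **not** contain: homologous sequence families,
post-translational cleavage and degradation (urinary peptides are heavily
degraded — the published method itself leaves this to future work),
probe-level microarray artifacts, or any real biology linking the protein
and expression layers. A green end-to-end test therefore establishes
pipeline correctness and the attainability of the published performance
*regime* (held-out sensitivity and specificity ≥ 0.90 under strong planted
signal), not reproduction of the published real-data figures.

## Numerical choices and degenerate inputs

* pI by bisection on the Henderson–Hasselbalch charge curve to
  $|Q|<10^{-4}$.
* MCC with any zero factor under the root reports 0 with an explicit
  degeneracy flag (the published MCC values are internally inconsistent with
  the published counts and formula, and are not targeted).
* AUC is the rank-based Mann–Whitney statistic; ties count one half.
* Instability index on length-1 sequences reports 0 with a warning; CTD
  distribution values on sequences shorter than 5 report 0 with a warning.
* Prediction labels positive at decision score ≥ 0; array confirmation and
  threshold filtering both use ≥ semantics at their boundaries.

## Known limitations

The feature heuristics are composition- and window-based stand-ins for
trained predictors; their absolute scores are not comparable to SignalP,
TMB-Hunt or FoldIndex outputs, only their ordering behavior is tested. The
secondary-structure estimate is composition-linear and cannot see long-range
structure. The permutation DE test's conservatism grows as the number of
fold-exceeding pairs shrinks. The SMO solver holds the full kernel matrix;
it is comfortable to a few thousand training rows and not beyond.
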
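---
title: "Methods: physicochemical encoding and LSTM classification of lysine glycation"
author: "glycLSTM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physicochemical encoding and LSTM classification of lysine glycation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycLSTM)
```

## The problem

Glycation is a nonenzymatic reaction of sugars and sugar-derived
dicarbonyls (notably methylglyoxal) with nucleophilic side chains,
primarily lysine, arginine and cysteine. It can culminate in advanced
glycation end-products that irreversibly impair protein function. No
sequence motif reliably marks glycation-prone lysines, but the
physicochemical character of the residues flanking a lysine appears to
matter. glycLSTM asks that question operationally: encode a 31-residue
window centered on a lysine by replacing each residue letter with a
numeric physicochemical value, train a recurrent classifier on labeled
windows, and compare how well different scales — alone, in pairs, or all
together — let the model separate glycated from nonglycated sites.

## Data model

A `PeptideSet` holds 31-mer windows over the 20-letter amino-acid
alphabet plus the pad symbol `X`, with `K` fixed at position 16 (1-based,
N- to C-terminal) and a binary label (1 glycated, 0 nonglycated, `NA`
unknown). Ambiguity codes (B, Z, J, U, O) are rejected rather than
imputed: the curated datasets this pipeline targets use the standard
alphabet, and silent imputation would blur the encoding semantics.
Windows extracted near protein termini are padded with `X` so the lysine
stays centered; protein coordinates in record ids are 1-based.

## The eight scales

`loadBuiltinPropertySet()` ships one lookup table per scale, in the fixed
canonical order SoA, Hyd, Mass, Hyp, Pol, vdW, ToA, IEP:

| id | meaning | default source | units |
|------|----------------------------------|------------------------------|-------|
| SoA | sequence-structure ordinal code | alphabetical rank 1–20 | – |
| Hyd | hydropathy | Kyte–Doolittle | – |
| Mass | residue mass | average residue masses | Da |
| Hyp | hydrophobicity | Fauchère–Pliška | – |
| Pol | polarizability | AAindex CHAM820101 | – |
| vdW | normalized van der Waals volume | AAindex FAUJ880103 | – |
| ToA | backbone conformational preference | Chou–Fasman helix propensity | – |
| IEP | isoelectric point | standard amino-acid pI | pH |

Two of these are deliberate, documented placeholders. "SoA" (the
"structure of the amino-acid sequence") has no standard numeric
definition; an ordinal code of the one-letter alphabet is used, which
preserves residue identity but imposes an arbitrary metric. For the
torsion-angle preference "ToA", several AAindex scales are defensible;
the Chou–Fasman helical propensity is used as a backbone-conformation
proxy. Both — and any other scale — can be replaced wholesale by editing
a single TSV and calling `loadPropertyTableFile()`, which validates
completeness (exactly the 20 standard residues, all eight columns,
numeric cells) and round-trips exactly through `writePropertyTable()`.

## Standardization

Raw scales differ by orders of magnitude (residue masses near 130 Da vs
polarizabilities near 0.2), which would saturate tanh units and let one
column dominate gradients. Each scale is therefore z-scored with
`fitScaleStats()`, which computes the mean and standard deviation over
all non-pad residue positions of the *training split only*; validation
and test windows reuse those statistics. The pad symbol always encodes
as 0 — the population center after standardization — so terminal padding
is neutral rather than extreme. Standardization is affine, so it never
changes the ranking of residues within a scale.

## Encodings: the three cases

* **Case 1** (one scale): a 31×2 matrix whose first column holds the
  standardized scale value at each window position; the second column
  duplicates the first. The duplication is implemented literally: it
  keeps the input width — and therefore the model's parameter count —
  identical between cases 1 and 2, so their comparison reflects the
  information content of the encoding, not model capacity.
* **Case 2** (two distinct scales): 31×2, one scale per column. All
  `choose(8, 2) = 28` unordered pairs are enumerated in lexicographic
  order by canonical scale position; `(a, b)` and `(b, a)` are the same
  subcase.
* **Case 3** (all eight): 31×8, columns in canonical order.

Rows are fed N- to C-terminal. Encoding never reads labels, and case-2
and case-3 columns are exactly the corresponding case-1 columns — both
properties are enforced by tests.

## The classifier

The model is a fixed stack: `LSTM(64, tanh)` → dropout → `LSTM(32)` with
the same configuration → dropout → `dense(16, ReLU)` → dropout → a
2-unit softmax giving `(p_nonglycated, p_glycated)` that sum to 1. Loss
is sparse categorical cross-entropy; the optimizer is Adam; mini-batches
hold 64 examples; training stops when validation accuracy has not
improved for 20 epochs and the best epoch's weights (earliest on ties)
are restored. The hard label is the argmax, with an exact tie called
nonglycated.

The engine is implemented in the package itself (RcppArmadillo,
single-threaded float32, full backpropagation through time). Every
stochastic element — Glorot-uniform initialization, per-epoch shuffling,
dropout masks — draws from one Mersenne Twister stream keyed by the
config seed, so a training run is exactly reproducible; repeat `r` of
subcase `s` in an experiment uses seed `baseSeed + 1000·s + r`.

Hyperparameters the protocol leaves open were fixed once as package
defaults, all configurable via `modelConfig()`:

* dropout 0.2 on all three dropout layers (a common regularization
  default; the architecture fixes placement, not rate);
* L2 coefficient 0.01 on the two LSTM input kernels ("linear regularized
  l2 type" is read as L2 weight regularization; both layers share the
  coefficient);
* Adam learning rate 1e-3 (the optimizer's canonical default);
* `maxEpochs = 200`, so patience-20 early stopping, not the cap,
  normally ends training (observed epoch counts on real-scale data sit
  well below this);
* forget-gate biases initialized at 1, a standard LSTM stabilizer.

## Evaluation protocol

Five confusion-matrix metrics — accuracy, precision, sensitivity,
specificity and the Matthews correlation coefficient — plus trapezoidal
AUC over a tie-grouped ROC staircase. MCC spans [−1, 1] with 0 the
chance-level expectation; it is the one metric sensitive to both
classes simultaneously. A metric whose denominator vanishes is reported
as 0 and flagged in an `undefined` attribute, keeping repeat averaging
total while staying auditable. Repeat summaries report the arithmetic
mean and the sample (n−1) standard deviation; means of per-run metrics
are reported (not metrics of pooled predictions), matching a protocol
that averages each metric over 20 training runs.

Splits are stratified by label only (4830/1000/1000 at full scale), and
`makeFolds()` builds 10 stratified folds whose sizes differ by at most
one. Stratification does not group homologous windows; the intended
inputs are already redundancy-reduced (CD-HIT at 30% identity), but with
raw data this is a potential leakage channel worth knowing about.
`crossValidate()` carves a stratified 15% internal validation subset out
of the training folds for early stopping, and its configuration-grid
hook ranks candidates by mean held-out sensitivity with accuracy as the
tiebreaker — a calibration that deliberately favors recovering true
glycation sites. All 20 repeats reuse one fixed split; redrawing splits
per repeat is possible by varying the split seed explicitly.

No-leakage is enforced mechanically: scale statistics and early stopping
see only training/validation data, and a canary test corrupts the test
labels and asserts that every training artifact (trained weights, scale
statistics) is bit-identical.

## Synthetic data: what it emulates and what it does not

The generator produces balanced 31-mer center-K windows with residues
drawn i.i.d. from a configurable background (uniform by default). The
planted signal mimics the scientific premise that flanking-residue
physicochemistry drives glycation: for a window, `z` is the standardized
mean of a planted scale over the `2·neighborhood` flanking residues (the
constant central K carries no information), and labels follow
`Bernoulli(plogis(beta·z))`, rejection-sampled to exact balance.
`generateSeparable()` is the infinite-`beta` limit (top half of `z`
labeled 1), and `generateNull()` assigns labels independently of
sequence. Neighborhood defaults to 15 (the whole window); 10 probes a
narrower microenvironment.

This emulates the structure the pipeline needs to be testable — balance,
window geometry, a property-linked effect of known size — but not real
proteomes: no residue-composition bias, no homology/clustering
structure, no mass-spectrometry detection bias, and a single planted
scale rather than correlated biochemical causes. Passing the planted
recovery tests therefore shows the pipeline can detect and rank a
property-linked signal when one exists; it does not certify real-data
accuracy.

One subtlety the synthetic experiments do expose: scales are correlated
across residues (lysine and arginine are extreme in both IEP and
polarizability), so a signal planted on IEP leaks weakly into encodings
of correlated scales. The planted-recovery criterion is about the
*ranking* margin, which stays decisive.

## Problem sizes and numerical choices

The verification suite scales the protocol down to desk scale, as its
own choice of problem size: the planted-recovery experiment uses
n = 4000 windows (2800/600/600 split), 3 repeats per subcase, 10 base
seeds, and a reduced training protocol (16/8/8 units, dropout 0.1,
L2 1e-4, learning rate 2e-3, `maxEpochs` 15, patience 5) — the smallest
stack that can represent the planted linear statistic, chosen a priori
so 8 subcases × 3 repeats × 11 datasets remain tractable on one CPU.
The full-scale defaults (64/32/16, patience 20, 20 repeats) remain the
package defaults used for real experiments.

Other numerical conventions: float32 arithmetic in the training engine
(like mainstream deep-learning defaults); softmax with max-subtraction;
`log(p)` clamped at 1e-12; exact probability ties classified as 0;
ranking ties broken by canonical scale order; zero-variance scales on a
training split raise an error rather than dividing by zero.

## Known limitations

* The built-in SoA and ToA scales are placeholders (see above); results
  for those subcases depend on that choice and should be read
  accordingly, or the scales replaced with transcribed values.
* The engine trains the fixed architecture only; there is no GPU path
  and no support for variable window lengths.
* Real-data headline numbers depend on externally hosted folds and
  unpublished hyperparameter values (dropout/L2/learning rate) and are
  therefore not reproduced by the test suite; the suite verifies the
  protocol and its statistical behavior instead.
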
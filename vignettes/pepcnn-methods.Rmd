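---
title: "Methods: peptide-MHC class I binding prediction in pepcnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide-MHC class I binding prediction in pepcnn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepcnn)
```

## The model

`pepcnn` fits one binary classifier per MHC class I allele that maps a
peptide of 8–15 residues to a binding probability. The pipeline has three
stages — length normalization, feature encoding, and a small
convolutional network — each of which involved genuine design choices;
this vignette records what was chosen, why, and what the package does and
does not demonstrate.

### Length normalization

Class I binding is dominated by a 9-residue core whose positions 1, 4, 6,
7 and 9 ("anchors") sit in the binding groove's specificity pockets. To
pool an allele's mixed-length data into one model, every peptide is
padded to a canonical 15mer with an artificial residue `X`, under one
hard constraint: the segments holding original residues 1–4 and 6–9 must
receive no internal `X`, so the anchor-bearing stretches stay contiguous.

The constraint does not pin down a unique placement, so the package fixes
the simplest deterministic rule that satisfies it:

* L ≥ 9: residues keep positions 1..L, positions L+1..15 are `X`;
* L = 8: residues 1–4 keep positions 1–4, a single `X` goes to position
  5 so residues 5–8 land on core positions 6–9, then right-pad.

Alternative placements (e.g. centring the padding gap for 10–12mers)
satisfy the same constraint; the rule lives in one function
(`normalize_to_15mer()`) precisely so it can be swapped without touching
anything downstream. Peptides outside 8–15, and any non-standard letter
(including ambiguity codes B/Z/U/J and `X` itself in raw input), are
rejected rather than coerced — silently mapping unknowns to `X` would
corrupt the padding semantics. All positions in messages and metadata are
1-based.

### Feature encodings

Two per-peptide matrices are available, plus their combination:

* **Substitution encoding** (15×21): row *i* is the BLOSUM62 row of the
  residue at padded position *i*, over the fixed 21-symbol alphabet
  (`A R N D C Q E G H I L K M F P S T W Y V X`). The matrix is extended
  by the rule that `X` scores 0 against every amino acid and 1 against
  itself, so padded positions carry a one-hot marker and no substitution
  signal. The 20×20 block is a versioned plain-text copy of the canonical
  NCBI BLOSUM62 shipped in `inst/extdata/` (and cross-checked against the
  independent copy in `Biostrings` by the test suite), rather than being
  taken from whichever library happens to be loaded — substitution-matrix
  variants drift, and the encoding must not.
* **Chemical-property encoding** (4×15): per position, the sequence
  index (1–21, dimensionless; 21 iff padded), the Eisenberg consensus
  hydropathy (dimensionless, range −2.5 for Arg to 1.4 for Ile; exactly 0
  at padded positions), the polarity class (0 padding, 1 non-polar,
  2 polar uncharged, 3 acidic, 4 basic), and the original peptide length
  (8–15, repeated across all 15 columns).
* **Stacked** (25×15): the transposed substitution encoding over the
  chemical rows.

All batch encodings are emitted channels × 15 so the two feature families
concatenate along the channel axis. Feature values are fed raw by
default: no standardization is described for this architecture, and the
adaptive optimizer copes with the heterogeneous scales (the sequence
index spans 1–21 while hydropathy spans ±2.5). An optional per-channel
standardization (`standardize = TRUE`) exists for experimentation but is
off in the faithful preset.

The default encoding is `chemical`: the 4×15 matrix is the pipeline's
novel feature and the network input shown in its data-flow description,
while the substitution encoding is retained as the conventional baseline
representation. All three modes are first-class; nothing downstream
assumes a particular channel count.

### The network

The faithful preset is fixed by the published architecture: **two
convolution layers of 20 filters each, ReLU activations, max pooling**,
then a dense head ending in a sigmoid probability. Details the
description leaves open are pinned as the smallest conventional
completion, all exposed in `pepcnn_config()`:

| parameter | default | rationale |
|---|---|---|
| convolution dimensionality | 1-D along the 15 positions | the 4 chemical rows are unordered categories, not a spatial axis; a 2-D kernel over them would mix index with hydropathy arbitrarily |
| kernel size | 3 positions | smallest kernel that sees a residue in context |
| pool size | 2 | halves the position axis twice: 15 → 13 → 6 → 4 → 2 |
| dense units | 64 | small head over the 40-unit flattened map |
| dropout | 0.25 | mild regularization on the dense head only |
| optimizer | Adam, lr 1e-3, batch 32 | standard small-network settings |
| epochs | up to 100, early stopping patience 10 | monitored on an internal 10% validation split; best-epoch weights are restored |
| seed | 42 | initialization, batching, dropout and the validation split all derive from it |

The engine is written in base R (`R/nn.R`): convolutions are im2col
matrix products, and the analytic gradients are verified against central
finite differences (relative error below 1e-4) in the test suite. With a
fixed seed two fits are bit-identical, which is the property the
evaluation layer builds on.

Degenerate inputs fail fast: fewer than two examples or a single class
refuse to train; a kernel or pool size that exhausts the 15-position axis
is a configuration error raised before training; a non-finite loss aborts
with the epoch in the message. Predictions are deterministic (dropout is
inference-off), so batch and one-at-a-time scoring agree to numerical
noise.

### Model scope

The published account is ambiguous between one model per allele (193
models) and four models per allele by length group (L ≤ 8, L = 9, L = 10,
L ≥ 11). The package defaults to **one model per allele across all
lengths** — the 15mer normalization exists precisely to enable pooling,
and per-allele data are often too sparse to split four ways. The
length-group reading is available as `pepcnn_lengthgroups()`, which
trains the four submodels, dispatches predictions by peptide length, and
falls back to the group base rate when a group is too small or
single-class to train.

## Data handling

IEDB-style tables (allele, peptide, measurement value / inequality /
type / source, original allele; comma- or tab-delimited) are read with
full quarantine accounting: every input row ends up either retained or
quarantined with a reason, never silently dropped.

Binary labels: quantitative affinities are thresholded at **500 nM**
(label 1 iff ≤ 500), the field's IEDB convention, since no explicit cut
is published for this pipeline; the threshold is an argument everywhere
it matters. Inequalities resolve only when they actually determine the
side of the threshold (`< 400` → binder; `> 20000` → non-binder;
`< 1000` is indeterminate against 500 and is quarantined). Qualitative
"Positive…"/"Negative" terms map to 1/0; eluted-ligand detections are
positives. Duplicate (allele, peptide) pairs keep one record, preferring
quantitative over qualitative over eluted-ligand provenance.

Alleles are retained only with **strictly more than 20** labeled
peptides, reading "larger than 20" literally (21 stays, 20 goes).
Cross-validation shuffles globally under a seed and cuts into k = 5
near-equal folds, remainder to the lowest-index folds for determinism; no
stratification by default (the published procedure only shuffles), with
stratified splitting behind a flag. Folds whose training data are
single-class are skipped and reported, never averaged silently.

## Metrics

F1 is computed as 2·TP / (2·TP + FN + FP) from counts at a probability
cut of 0.5 (the cut is itself a parameter, since the published account
never states how probabilities became class calls). A zero denominator —
possible only when there are no positives anywhere — returns 0 with a
`degenerate` flag rather than `NaN`, so cohort averages stay defined
without hiding the case. AUC is the rank-based Mann–Whitney statistic
with ties counted one half; single-class inputs are an error, not 0.
Cohort summaries use the sample standard deviation (n−1; 0 for a single
allele) and report the F1 distribution in three bands (< 0.5, 0.5–0.9,
> 0.9) and AUC in deciles.

## The synthetic generator

Real training corpora are external and versioned; the package instead
ships a seeded generator (`motif_spec()`, `generate_allele_dataset()`)
whose planted structure is recoverable by construction:

* positives draw their anchor residues (core positions 1, 4, 6, 7, 9)
  from small preferred sets with probability `motif_strength` (default
  0.9 — strong but not deterministic, so the learning task is
  non-trivial), the defaults being hydrophobic sets (L/I/V at 1 and 9,
  F/Y/W at 4, L/M/I at 6–7) in line with the general hydrophobic
  preference of class I ligands;
* non-anchor core positions of positives are tilted toward hydrophobic
  residues with weight `exp(hydropathy_bias × hydropathy)` (default bias
  1);
* positive lengths follow a 9mer-heavy distribution (55% 9mers; default
  chosen to resemble the length profile of class I ligand data), while
  negatives are uniform over lengths 8–15 and over the 20 residues;
* labels flip with probability `noise_rate` (default 0).

Setting `motif_strength = 0`, `hydropathy_bias = 0` and a uniform length
distribution makes positives statistically identical to negatives — the
null generator used to verify that the classifier reports chance-level
AUC when there is nothing to learn. `write_iedb_like_table()` serializes
a synthetic dataset as a measurement table with affinities synthesized on
the label-consistent side of the 500 nM cut, so the entire real-data path
(read → label → filter → split) is exercised in tests.

What the generator does **not** emulate: real allele motifs (no attempt
at, say, A*02:01's anchor preferences), assay noise structure,
inequality-censored measurements, class imbalance across alleles, or
mass-spectrometry detection bias. Passing the synthetic-recovery tests
therefore shows that the implementation can learn a planted signal of the
kind the method targets — it says nothing about accuracy on real IEDB
data, whose published summary figures depend on specific corpus snapshots
and are out of scope here.

## Numerical choices and problem sizes

* Probability clamping at 1e-12 in the cross-entropy; He-initialized
  weights; early-stopping improvements must exceed 1e-6 to reset
  patience.
* Top-fraction selection takes the ceiling of fraction × N and breaks
  score ties by stable input order (R's radix order), so the
  2%-of-10,000 selection is exactly 200 peptides.
* The length-preference probe defaults to 1,250 peptides per length 8–15
  (10,000 total), residues uniform unless a background table is given.
* Test and acceptance runs use n = 2000 synthetic examples for the
  recovery checks (about half a minute end to end), n = 200–800 for
  training-dynamics and fixture models, and exhaustive enumeration for
  the metric oracles (all confusion matrices with entries ≤ 20; pair
  counting at up to 12 examples). These sizes were chosen as the
  smallest at which the planted-signal checks are comfortably stable
  across seeds.

## Known limitations

* No pan-allele transfer: alleles are independent models, so rare
  alleles get weak models (mirroring the allele-specific approach).
* The placement rule for padding 10–12mers is one consistent reading of
  the anchor-contiguity constraint, not a verified transcription of the
  original figure.
* The CNN engine is CPU-only base R; it is sized for per-allele datasets
  (thousands of peptides), not for corpus-scale pretraining.
* Quantitative labels ignore measurement uncertainty; an affinity of
  499 nM and 3 nM are the same positive.
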
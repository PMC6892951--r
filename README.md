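# pepcnn

Peptide–MHC class I binding prediction with a small convolutional network
trained on chemical-property features.

## The problem

MHC class I molecules present short peptides (8–15 residues) on the cell
surface; predicting which peptides an HLA allele binds is the central step
in epitope discovery and peptide-vaccine design. Binding specificity is
dominated by the anchor positions of the 9-residue binding core (positions
1, 4, 6, 7 and 9), but measured ligands come in mixed lengths, so a
predictor that wants to pool all of an allele's data must first put
peptides of different lengths on a common footing.

`pepcnn` is for immunoinformaticians who want a self-contained, fully
reproducible implementation of this allele-specific approach:

1. **Length normalization.** Every 8–15mer is padded to a canonical 15mer
   with an artificial residue `X` placed so that the anchor segments
   (original residues 1–4 and 6–9) stay contiguous. For L ≥ 9 the peptide
   is right-padded; an 8mer takes a single `X` at position 5 so residues
   5–8 shift onto core positions 6–9.
2. **Feature encoding.** Two per-peptide matrices: a 15×21 extended
   BLOSUM62 encoding (row *i* is the substitution row of the residue at
   position *i*; `X` scores 0 against everything and 1 against itself),
   and a 4×15 chemical-property matrix whose rows are the sequence index
   (1–21), the Eisenberg consensus hydropathy (X = 0), the polarity class
   (0–4), and the original peptide length repeated across positions.
3. **Model.** Per allele, a convolutional classifier
   `conv(20 filters) → ReLU → maxpool → conv(20 filters) → ReLU → maxpool
   → dense(64) → sigmoid`, applied as 1-D convolutions along the 15
   positions with the feature rows as channels, trained with binary
   cross-entropy (Adam, early stopping). The network is implemented in
   base R and is exactly reproducible under a seed.
4. **Evaluation.** Shuffled five-fold cross-validation per allele with
   F1 = 2·TP / (2·TP + FN + FP) at a 0.5 probability cut and rank-based
   ROC-AUC, plus cohort summaries (mean / median / SD and banded
   distributions) across alleles.
5. **Length-preference probe.** 10,000 random peptides (1,250 of each
   length 8–15) are scored by a trained model; the length distribution of
   the top 2% reveals which peptide lengths the allele model prefers.

A seeded synthetic-data generator with a planted anchor motif, hydropathy
bias and length preference makes the whole pipeline testable without any
external download.

## Worked example

```r
library(pepcnn)

ds  <- generate_allele_dataset(motif_spec(), n = 2000, seed = 11,
                               allele = "SYN-A*02:01")
fit <- pepcnn(label ~ peptide, data = ds$examples, allele = "SYN-A*02:01")
fit
#> Peptide-MHC binding CNN [SYN-A*02:01]
#>   encoding: chemical (4 x 15)
#>   architecture: conv(20) -> relu -> maxpool -> conv(20) -> relu -> maxpool -> dense(64) -> sigmoid
#>   trained on 2000 peptides (1000 positive), 56 epochs, final loss 0.06577

summary(fit)
#>   parameters: 4169
#>   training F1 (cut 0.5): 0.9741, training AUC: 0.9968

round(predict(fit, c("SLFEKLIAV", "QQQDDDNNK")), 3)
#> [1] 0.745 0.000
```

The first peptide carries the planted hydrophobic anchors (L/I/V at core
positions 1 and 9), the second is hydrophilic at every anchor, and the
fitted probabilities separate them accordingly. Probing the model's
length preference:

```r
length_preference(fit, seed = 7)
#> Length preference [SYN-A*02:01]: top 200 peptides
#>  length count proportion
#>       8    17      0.085
#>       9    78      0.390
#>      10    35      0.175
#>      ...
#>   modal length: 9
```

The generator plants a 9mer-heavy length distribution among binders, and
the probe recovers a 9-modal preference — the qualitative behaviour
expected of class I alleles.

The same workflow is scriptable from a shell via the installed
`exec/pepcnn` entry point (`synth`, `encode`, `train`, `evaluate`,
`lengthpref` subcommands).

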
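# glycLSTM

Predicting nonenzymatic **lysine glycation** from protein sequence
context. Glycation — the reaction of sugars and reactive dicarbonyls such
as methylglyoxal with lysine/arginine/cysteine side chains — has no clean
sequence motif, but the physicochemical character of the residues
flanking a lysine carries signal. glycLSTM is for computational
proteomics researchers who want to quantify *which* physicochemical
scales carry that signal, using a controlled, fully reproducible
recurrent-network protocol.

## What it does

Each candidate site is a 31-residue window with the lysine at position
16. The window's letters are replaced by numeric values from eight
physicochemical scales — sequence-order code (SoA), hydropathy (Hyd),
residue mass (Mass), hydrophobicity (Hyp), polarizability (Pol),
normalized van der Waals volume (vdW), backbone torsion preference
(ToA) and isoelectric point (IEP) — z-scored with training-split
statistics. Three comparative designs feed a compact LSTM classifier:

* **Case 1** — one scale, duplicated into a 31×2 input (8 subcases);
* **Case 2** — each of the 28 unordered scale pairs as 31×2 (28 subcases);
* **Case 3** — all eight scales as 31×8 (1 subcase).

The classifier is `LSTM(64, tanh) → dropout → LSTM(32) → dropout →
dense(16, ReLU) → dropout → softmax(2)`, trained with sparse categorical
cross-entropy and Adam (batch 64), early-stopped on validation accuracy
with patience 20 and best-epoch restoration. Each subcase is trained
repeatedly (20 repeats at full scale) and scored on an independent test
split with accuracy, precision, sensitivity, specificity, the Matthews
correlation coefficient

MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))

and trapezoidal ROC/AUC; subcases are ranked by repeat-averaged metrics.
Stratified 4830/1000/1000 splits and 10-fold cross-validation (with a
sensitivity-first configuration grid hook) implement the evaluation
protocol. The training engine is part of the package (RcppArmadillo,
single-threaded float32, fully seeded), so identical seeds give
bit-identical runs.

A synthetic generator produces balanced center-K windows whose label
depends on a planted scale of the flanking residues through a logistic
link (`label ~ Bernoulli(plogis(beta * z))`), which makes the entire
pipeline verifiable end-to-end without any downloads.

## Worked example

Plant a glycation signal on the isoelectric point of the flanking
residues, then ask Case 1 which of three scales explains the labels:

```r
library(glycLSTM)

ps <- loadBuiltinPropertySet()
cfg <- syntheticConfig(n = 2000, plantedProperties = "IEP", beta = 3, seed = 42)
peptides <- generatePlanted(cfg, ps)
print(peptides)
#> PeptideSet with 2000 31-mer window(s): 1000 glycated, 1000 nonglycated, 0 unlabeled
#>   first: syn_1  YLANIQGCFPMKCAEKRTIVIRWLLLQCLRI

split <- makeSplit(peptides, sizes = c(1400, 300, 300), seed = 42)
plan <- experimentPlan(repeats = 2L, baseSeed = 42L,
                       modelConfig = modelConfig(lstm1 = 16L, lstm2 = 8L, dense = 8L,
                                                 dropout1 = 0.1, dropout2 = 0.1, dropout3 = 0.1,
                                                 l2 = 1e-4, learningRate = 2e-3,
                                                 maxEpochs = 15L, patience = 5L))
result <- runCase1(split, ps, plan, properties = c("Mass", "ToA", "IEP"))
result@summary[, c("subcase", "accuracy_mean", "mcc_mean", "auc_mean")]
#>   subcase accuracy_mean mcc_mean auc_mean
#> 1    Mass         0.575   0.1545    0.609
#> 2     ToA         0.487  -0.0279    0.476
#> 3     IEP         0.840   0.6823    0.915
result@ranking
#> [1] "IEP"  "Mass" "ToA"
```

IEP — the scale the signal was planted on — wins decisively (84% test
accuracy, MCC 0.68, AUC 0.92). Mass picks up a weak echo because scales
are correlated across residues (K and R are extreme in several of them);
ToA, uncorrelated with the planted signal, stays at chance. On real
curated data the same machinery reports which scales are most
informative for actual lysine glycation; `exportResults()` writes the
per-subcase metric tables, ROC points and a provenance JSON, and
`cmdPredict()`/`exec/glyclstm predict` scores every lysine of a protein
FASTA with a saved model.

## Scale provenance

Built-in scales are canonical literature values (Kyte–Doolittle
hydropathy, Fauchère–Pliška hydrophobicity, average residue masses,
standard isoelectric points, AAindex polarizability and van der Waals
volume, Chou–Fasman helix propensity as the torsion-preference proxy,
and an ordinal code for SoA). The SoA and ToA defaults are documented
placeholders — see the methods vignette — and any scale can be replaced
from a TSV via `loadPropertyTableFile()`.
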
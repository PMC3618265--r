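---
title: "Affinity-thresholded drug-target interaction screening: models and methods"
author: "dtiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Affinity-thresholded drug-target interaction screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`dtiscreen` predicts drug–target interactions from quantitative binding
affinities. The package covers the full path from raw inputs (FASTA
protein sequences, SMILES drug structures, Ki tables) to an
FDR-calibrated bipartite interaction network, plus a synthetic
benchmark generator that makes every stage testable without external
database downloads. This vignette documents the models, the tunable
parameters and their defaults, the numerical conventions, and the
limits of what the synthetic validation shows.

## Labelling pairs by binding affinity

Ki — the concentration of a competing ligand that occupies half the
receptors in a competition assay — quantifies binding tightness; nM-level
inhibitors bind tightly, μM-level ones moderately. `dtiscreen` stores
all Ki in nanomolar and labels a (drug, target) pair an *interaction*
when its Ki lies strictly below a threshold, 10 μM (10,000 nM) by
default. A pair with Ki exactly at the threshold is a negative; the
positive set therefore grows monotonically with the threshold, which
`threshold_sweep()` exploits to study label-definition sensitivity.

Raw tables often carry several Ki records per pair (different assays or
sources) and records from non-human orthologs. `aggregate_ki()` takes
the median per pair (mean of the two central values for even counts —
the ordinary sample median), and `filter_species()` removes records
whose free-text species annotation contains, case-insensitively, any of
the keywords rat, rabbit, bovine, sheep, calf, pig, mouse, guinea pig,
dog or undefined. Substring matching was chosen because annotations are
free text ("Bos taurus bovine"); records with no species field are
kept, since an absent field more often means an unannotated human assay
than an undefined organism. Unit conversion (nM/μM/M) is explicit via a
declared unit column — never guessed from magnitudes.

## The pair feature space

**Protein block (167 values).** Seven physicochemical properties each
divide the 20 amino acids into three groups (the standard three-group
divisions used throughout the CTD literature; the hydrophobicity
division — polar RKEDQN, neutral GASTPHY, hydrophobic CLVIMFW —
reproduces the canonical worked encoding of `MTEITAAMVKELRESTGAGA`
exactly, which pins the convention). For each property the sequence is
rewritten over {1,2,3} and summarised by 21 descriptors: 3 composition
percentages, 3 transition percentages (adjacent pairs switching between
two given groups, normalised by N−1), and 15 distribution percentages —
for each group, the chain position (as % of N) of its first, 25%, 50%,
75% and 100% occurrence. The occurrence index for fraction f is
`max(1, floor(f * n_g))`; this rule is adopted because it uniquely
reproduces every printed value of the canonical worked example
(e.g. with n=10 occurrences the 25% index is 2 and the 75% index is 7).
A group absent from the sequence contributes five zeros, keeping the
vector length fixed. The 7×21 = 147 CTD values are followed by the
20 amino-acid composition percentages; properties appear in the fixed
order hydrophobicity, normalized van der Waals volume, polarity,
polarizability, charge, secondary structure, solvent accessibility.
The block order (CTD then AAC) and the percent scale of AAC are package
conventions, exposed through `protein_index_map()` so ablation studies
can address any block.

Non-standard residues (X, B, Z, U, gaps) are rejected by default with
the offending character and position; an opt-in `"strip"` policy
removes them first, which is convenient for fragment databases but
slightly biases composition — hence not the default.

**Drug block (1024 bits).** SMILES are parsed with OpenBabel (via
ChemmineR/ChemmineOB). All linear paths of 2–7 heavy atoms are
enumerated by depth-first search without revisiting atoms; each path is
typed as an alternating atom/bond string and read in its
lexicographically smaller direction, making the fingerprint a function
of the molecular graph rather than of the input atom order. Each
canonical path is hashed with a deterministic polynomial string hash
(mod 2³¹−1, all-double arithmetic, hence platform independent) and
folded into a 1024-bit array. Kekulized bond orders as emitted by the
parser depend on SMILES atom order, so aromatic rings are re-perceived
and their bonds typed 'a' (default `bond_typing = "aromatic"`); raw
kekulized orders (`"kekule"`) and element-only paths (`"none"`) are
selectable because the literature is silent on whether aromatic
perception should enter path canonicalization. Stereochemistry is
ignored. `nbits`, `min_path` and `max_path` are parameters; one-atom
molecules have no 2-atom path and yield the zero vector, for which the
Tanimoto similarity is defined as 1 against another zero vector.

Bit-exact reproduction of any particular toolkit's fingerprint is *not*
a goal; the contract is determinism, atom-order invariance, and the
similarity-principle behaviour verified in the tests. The convention is
recorded in the fingerprint's `params` attribute.

The pair vector concatenates drug bits then protein descriptors:
1024 + 167 = 1191 dimensions.

## Classifier

`dti_rf()` grows 600 classification trees on bootstrap samples,
considering `mtry` random features per split with the Gini criterion
(backed by the `ranger` engine; the contract — bootstrap per tree, Gini
splits, OOB estimates, vote-fraction probabilities, permutation
importance — is what the test suite pins, not tree internals). The
predicted probability is the fraction of tree votes for the positive
class, not leaf-probability averaging; this is recorded in the model
object. 600 trees is the convergence default: on the benchmarks the OOB
error changes by less than 0.01 between 400 and 600 trees. `tune_mtry()`
screens 5–100 in steps of 5 (default grid), refitting each candidate
five times with derived seeds and scoring by mean OOB
misclassification; OOB is used rather than cross-validated error
because it comes free with each fit. Ties break toward smaller `mtry`
(cheaper, more decorrelated trees). Training is on the label
distribution as-is — no reweighting by default, because the affinity
threshold defines the prevalence of interest — with an optional
`class_weights` argument.

Permutation importance (each feature perturbed in turn on OOB samples,
quality drop = score) drives `select_top_features()`, whose
deterministic index tie-break makes reduced-model experiments
reproducible.

`dti_nb()` is the comparison baseline: an independence model with
Laplace-smoothed Bernoulli likelihoods for binary columns (the
fingerprint bits) and Gaussian likelihoods (variance floored at 1e−9)
for continuous columns, accumulated in log space with a log-sum-exp
posterior. Because the planted synthetic signal is an *interaction*
between drug class and target family, the independence assumption
costs the baseline most of its discrimination — mirroring the general
observation that integrated features act cooperatively.

One master seed derives all child seeds (fold assignment, per-fold
models, generator stages) through a fixed string-salted hash, so the
entire generate → featurize → train → predict → screen path is
byte-reproducible.

## Evaluation machinery

`kfold_cv()` uses stratified folds (sizes differing by at most one,
class counts per fold within one) and pools out-of-fold probabilities so
each pair is predicted exactly once. `curves_and_areas()` computes the
ROC by threshold sweep with tied scores collapsed into single operating
points (trapezoidal auROC — equal to concordant-pair counting with ties
at one half, which the tests verify against a brute-force oracle) and
the precision–recall curve with area as average precision (step
integral). `confusion_at_threshold()` counts score ≥ threshold as
positive (ties to positive). `ki_probability_correlation()` reports the
signed Pearson correlation of log10(Ki) with probability — base 10
because affinities are conventionally discussed in decades (nM vs μM);
a well-calibrated model gives a negative sign (tight binders, high
probability).

## FDR calibration and screening

At a probability cutoff t, the empirical false discovery rate among
predicted positives is FDR(t) = FP/(FP+TP), computed from pooled
cross-validation predictions. Since precision = 1 − FDR at every
cutoff, this is the same information as the precision–recall curve read
backwards. `fdr_calibration()` enumerates every unique score as a
candidate cutoff and returns, per requested level, the *smallest*
cutoff with FDR ≤ level — smallest because recall is non-increasing in
the cutoff, so the smallest qualifying cutoff maximises recall. Note
that FDR(t) is not monotone in t, so an exhaustive scan (verified
against an independent enumeration oracle in the tests) rather than a
bisection is used; levels that no cutoff attains are reported
unattainable, never clamped. `screen_matrix()` fills the full
drug × target probability matrix in memory-bounded chunks, cell (i, j)
being exactly the pairwise prediction; `novel_edges()` thresholds it,
excludes training pairs on exact id match (no structural
deduplication), and `export_network()` writes SIF, GraphML (bipartite
`type` attribute) and CSV with a degree summary.

## The synthetic benchmark

The generator plants a recoverable ground truth. Targets come in
families; family f draws each residue from its enriched hydrophobicity
group with probability `group_bias` (default 0.5) and uniformly
otherwise, so families differ in CTD composition. Drugs come in classes
sharing a core ring fragment (benzene, cyclohexane, pyridine,
tetrahydrofuran, ...) decorated with random chain fragments from a
grammar that can only produce valid SMILES. Each (class, family) cell
of an affinity matrix gives the mean log10(Ki/nM);
`log10(Ki) = mean + N(0, noise_sd)`. The log-normal form makes log(Ki)
the natural scale and concentrates labelling errors near the threshold,
where real assay data are also most ambiguous.

The `"strong"` preset is the package's reference condition: 4 families
× 5 targets (sequences 200–400 residues), 4 classes × 15 drugs, matched
class/family mean log10 Ki = 2 (~100 nM, tight), mismatched 5
(~100 μM, weak), noise SD 0.5 — so with the 10 μM threshold roughly a
quarter of the 1200 pairs are positive, with genuine label noise at the
margins. The `"null"` preset sets every mean to 3.5 so labels are
independent of the features. Under the strong preset the full pipeline
reaches five-fold CV auROC ≈ 0.96 and |r| ≈ 0.86 for the
log10(Ki)–probability correlation; under the null preset auROC sits
within sampling noise of 0.5. These problem sizes run the entire
acceptance suite in a few minutes on one CPU while keeping all effects
many standard errors away from their test bounds.

What the synthetic validation does **not** show: real drugs are not
built from a six-core grammar, real protein families differ in far more
than one property-group composition, real Ki tables have skewed,
heteroscedastic replicate structure, and real screening matrices are
three orders of magnitude larger. Passing the synthetic suite
demonstrates that the machinery is correct and that planted signal of
realistic effect size is recovered — not that any particular accuracy
will be achieved on a given real data set.

## Numerical conventions and degenerate inputs

* Descriptors are computed and compared at full double precision;
  2-decimal rounding is display-only (half-up).
* Transition requires N ≥ 2; empty sequences and single-class label
  vectors are rejected, not silently handled.
* A Ki threshold must be strictly positive; thresholds that leave one
  class during a sweep are skipped with a warning.
* Probability ties at a decision threshold count as positive.
* All randomness flows from one integer master seed; derived seeds stay
  below 2³¹.

## Known limitations

* The fingerprint hash is package-specific: fingerprints are comparable
  within `dtiscreen` runs, not across toolkits.
* Stereochemistry and tautomerism are invisible to the drug block.
* The species filter is a keyword heuristic, not a taxonomy mapping.
* FDR calibration assumes the screened population resembles the
  cross-validated training distribution; strong covariate shift between
  training pairs and the screening universe will bias the calibrated
  FDR.
* Naive Bayes assumes feature independence; it is included as a
  baseline, not as a recommended model.
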
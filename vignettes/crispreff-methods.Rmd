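---
title: "Methods: sgRNA sequence features and cleavage efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sgRNA sequence features and cleavage efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispreff)
```

## The problem

SpCas9 is directed to a genomic target by a single guide RNA (sgRNA) whose
20-nt guide sequence base-pairs with the protospacer, 5' of an NGG PAM. In
practice guides vary enormously in on-target cleavage efficiency, and
enzyme-mismatch assays (Surveyor) give a binary readout: cleaved or not.
`crispreff` implements a complete analysis relating guide features to that
binary outcome: position-wise nucleotide composition tests with a
permutation family-wise correction, GC-window features, secondary-structure
features of the full sgRNA, and a dummy-coded logistic model evaluated by
ROC/AUC both on the training data and under cross-validation. A synthetic
generator with known ground truth makes every stage testable end to end.

## Coordinate and position conventions

Genomic coordinates are 0-based half-open (BED convention) internally;
1-based tables are converted at parse time. Sequences may be given in RNA
notation; U is normalized to T on input. Analysis positions run 1..21:
positions 1..20 are the guide 5'->3', so position 20 is the base
immediately adjacent to the PAM, and position 21 is the variable N base of
the PAM itself. The published occurrence tables this pipeline mirrors run
to 21 rows while the guide is only 20 nt; treating row 21 as the PAM N base
is a deliberate interpretation — the transcribed extra 5' G (the "G" of
GN20, required by the U6 promoter) is constant and cannot show the
variation those tables report, whereas the PAM N base can. The GN20
transcript is carried separately as `extended_seq` and used only for
folding.

## Composition statistics

Per outcome group, `count_nucleotides()` tabulates A/C/G/T occurrences at
each of the 21 positions; `frequency_delta()` gives the
positive-minus-negative frequency matrix used for the heatmap (rows sum to
zero by construction). At each position `chisq_position()` runs the Pearson
chi-square homogeneity test on the 2 x 4 group-by-base table with **no**
continuity correction and df = 3. This is the convention under which the
reference occurrence table's printed p-values reproduce exactly (R applies
Yates' correction only to 2 x 2 tables). A base absent from both groups is
dropped and df reduced; expected cells below 5 are flagged, not fatal,
since real guide tables contain such cells.

The family-wise correction is minP: `minp_permutation()` reassigns the
outcome labels at random `n_perm` times (default 10,000) preserving group
sizes, records the minimum p across all 21 positions in each permutation,
and compares each observed raw p to that null distribution of minima. Two
estimators are offered: the default add-one form (r + 1)/(n_perm + 1),
which avoids exact zeros, and the plain tail fraction r/n_perm; at
n_perm = 10,000 the difference is below printed precision. Because column
totals are invariant under label permutation, expected counts are
precomputed once and the permutation loop is vectorized; a seed is a
required argument, since the analysis is otherwise not reproducible.

## GC features

GC percentages are computed on the 20-nt guide only — the U6 G and PAM are
excluded — overall and over the windows 1–6, 7–14 and 15–20. The
"GC normal" indicator is the inclusive band 40% <= GC <= 60%; the
published description does not state whether the bounds are inclusive, and
the conventional inclusive reading was adopted (boundary cases are
unit-tested at exactly 40 and 60). Group comparisons use the Welch
unequal-variance t-test and the two-sample Kolmogorov–Smirnov test.

## Secondary-structure features

Three feature families are computed from equilibrium RNA folding:

* **MFE** of the full sgRNA (GN20 + scaffold), a global stability measure;
* **seed accessibility**: the probability that the 12 PAM-proximal guide
  bases are simultaneously unpaired, averaged over all sliding windows of
  width W = 21 (the GN20 length) that contain the seed, each window folded
  in isolation — the local-folding construction used by RNAplfold-style
  accessibility calculations;
* **guide–tracrRNA interaction**: from the base-pair probability matrix of
  the concatenated molecule, each scaffold base's maximum and average
  pairing probability with guide bases, both averaged over scaffold bases.
  Both aggregations are emitted; the model consumes whichever columns the
  caller passes.

The default folding substrate for accessibility is the full sgRNA: a
width-21 sliding window is only meaningful on a sequence longer than 21 nt,
so scanning GN20 alone would degenerate to a single window. The seed length
U is a parameter, so a whole-guide (U = 21) variant is available.

The internal backend is a McCaskill-style partition function over nested
structures with Watson–Crick + GU pairs, additive per-pair energies
(defaults GC = −3, AU = −2, GU = −1 kcal/mol), no loop or stacking terms, a
minimum hairpin loop of 3, and Boltzmann factor exp(−E/RT) at 37 °C
(RT ≈ 0.616 kcal/mol). This model was chosen because the package's feature
definitions are aggregation formulas over *any* valid base-pair probability
source, and a deliberately simple energy model admits an exhaustive
enumeration oracle: the test suite lists every nested structure of random
sequences up to length 14 and checks pair probabilities, MFE and
constrained-unpaired probabilities to 1e-9. Constrained quantities come
from the ratio of a partition function with the span's bases forbidden to
pair to the unconstrained one. An external backend shells out to `RNAfold`
(ViennaRNA) for Turner-parameter energies — MFE from its output, pair
probabilities from its dot-plot file, constrained ensembles via hard
constraints — and reports explicitly when the executable is unavailable.
Internal energies are not on the Turner scale, so absolute MFE values
differ between backends; within one backend the features are comparable
across guides, which is what the regression consumes. The Boltzmann
temperature is exposed: lowering it concentrates the ensemble on the MFE
structure, a property the tests exploit.

The scaffold is data, not code: the packaged default is the standard
chimeric crRNA–tracrRNA scaffold of pX330-type SpCas9 constructs (76 nt),
and any FASTA can be substituted.

## The efficiency model

Nucleotides are dummy-coded per position; the baseline level at each
position is the base with the smallest absolute frequency delta between
outcome groups (ties broken alphabetically — the tie rule is not stated in
the source convention and had to be fixed somewhere). Genomic context
enters as six dummies with intergenic as baseline; GC enters as the binary
`gc_normal` (the continuous percentage is available to callers by passing
it as a feature column); structure covariates enter untransformed.

`fit_logistic()` is plain maximum likelihood via IRLS (`stats::glm`,
binomial family) with Wald standard errors, z = estimate/SE and two-sided
normal p-values — no regularization, matching the source analysis.
Separation and non-convergence are surfaced as attributes rather than
silently returned, and aliased (rank-deficient) columns are reported as
dropped; an explicit `ridge = TRUE` flag provides an L2-penalized fallback
(glmnet) without Wald statistics for separated data.

Evaluation follows two settings: the ROC curve and trapezoidal AUC of the
full-data fit applied back to its training data (optimistic by
construction), and the mean AUC over stratified k-fold cross-validation
(default k = 20) in which the per-position baselines are re-chosen from
each training split. The AUC implementation integrates the ROC curve over
distinct thresholds; by construction this equals the pairwise concordance
probability with ties counted half, and the tests verify that identity
against a brute-force O(n^2) oracle. Folds are stratified by outcome —
whether the source analysis stratified is unknown, but stratification is
the only choice that keeps 20 folds scorable at 218 records — and fold
assignments whose held-out part lacks a class are re-drawn with a warning.

The open-chromatin association (`context_dhs_association()`) cross-tabulates
"annotated promoter-TSS" against "overlaps a DNase-hypersensitive site"
(strand ignored: accessibility is strand-agnostic) and reports both the
chi-square test (R's default Yates correction for 2 x 2) and Fisher's
exact test, the latter alone when a margin is degenerate.

## The synthetic generator

`generate_dataset()` draws guides i.i.d. per position (uniform by default;
a "paperlike" preset uses the pooled marginal base frequencies of the
packaged occurrence fixture), contexts from a seven-category distribution,
and the outcome from a Bernoulli–logistic model whose linear predictor sums
an intercept, per-(position, base) effects, context effects, a `gc_normal`
effect and structure-covariate effects. Defaults mirror the reference
study's conditions: 218 records, and effect magnitudes of the order of the
published fit (`gc_normal` +3.1, adenine at position 20 −2.2, promoter-TSS
+3.9, seed accessibility −9). The default context distribution (intron
0.35, intergenic 0.30, exon 0.12, promoter-TSS 0.10, TTS 0.05, 3'UTR and
5'UTR 0.04 each) is a realistic genome-wide annotation mix chosen once;
the source only reports its distribution graphically. The default
intercept 2.74 is calibrated so that, under the default noise-mode
covariate distributions, about 59% of outcomes are positive — the
reference study's 129/218 split. Structure covariates come either from
really folding the generated sequences ("fold" mode, giving the model
stage realistic collinearity) or from plausible noise distributions
("noise" mode, for speed at large n). Under fold mode the internal energy
model leaves the seed almost always paired (seed accessibility near 0), so
reproducing the 59% split there requires a lower intercept (about −1.8);
the demo script does exactly that.

What the generator deliberately does **not** emulate: Surveyor assay noise
and gel-interpretation ambiguity; linkage between neighbouring positions
(real guides are genomic sequence, not i.i.d. draws); chromatin state tied
to genomic coordinates; and any relation between coordinates and sequence.
Passing tests on synthetic data therefore demonstrate the statistical
machinery, not biological validity on real guides.

## Numerical choices and problem sizes

Permutation p-values use the add-one estimator by default (see above).
Chi-square positions with a base absent from both groups reduce df; a
position with a single shared base returns p = 1. The engine's
enumeration-oracle tolerance is 1e-9; closed-form logistic checks use
1e-8. The test suite's simulation sizes were chosen to keep the full run
around a minute while leaving Monte-Carlo error well inside the asserted
bands: 10,000 permutations against exhaustive enumeration on 6–8-record
toys, 100 random sequences up to length 14 for the folding oracle, 100
random instances up to n = 500 for the AUC oracle, and 200 replicates of
n = 5,000 for Wald-coverage of recovered coefficients (asserted within
three binomial standard errors of 95%).

## Limitations

The internal energy model is intentionally minimal: no stacking, loop
entropies, dangles or pseudoknots; use the ViennaRNA backend where
Turner-scale energies matter. The published permutation-adjusted p-values
and fitted coefficients of the reference study cannot be recomputed here
because they require its per-guide supplementary dataset; the package
reproduces everything derivable from the published per-position counts
(all 21 raw chi-square p-values and all printed frequencies) and validates
the rest against oracles and ground-truth simulations. Quantitative
(non-binary) efficiency outcomes are out of scope.
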
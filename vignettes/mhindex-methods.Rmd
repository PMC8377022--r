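---
title: "Methods: enterotype discovery, biomarker selection and the MHI classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enterotype discovery, biomarker selection and the MHI classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhindex)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the parameters that matter, the numerical
conventions, and what the synthetic-cohort tests do and do not demonstrate
about real data.

## Data model

The substrate is a samples × taxa matrix of counts or relative abundances
(`abundance_table`), each column carrying a taxonomic lineage ordered
kingdom → genus. A taxon classified only to some higher rank is displayed at
lower ranks as that ancestor's name with an asterisk (`Enterobacteriaceae*`
is "an unclassified genus of family Enterobacteriaceae"); two unclassified
groups merge only if they share the same nearest classified ancestor.
Aggregation to a rank sums columns and conserves per-sample totals to 1e-9.
Relative-abundance rows must sum to 1 within 1e-9; conversion from counts is
idempotent and refuses all-zero samples by name.

Alpha diversity (observed taxa, Shannon index on natural logarithms) is
computed after rarefaction to 4000 reads, the depth at which rarefaction
curves of typical 16S ICU libraries plateau. Samples below the depth are
dropped from alpha diversity only — never from enterotyping, which uses
unrarefied relative abundances (the protocol ties the 4000-read depth to
diversity estimation, not to clustering).

## Enterotype discovery

Between-sample dissimilarity is the Jensen-Shannon **distance**,
$d(x,y)=\sqrt{\tfrac12 KL(x\|m)+\tfrac12 KL(y\|m)}$ with $m=(x+y)/2$.
Logarithms are base 2, so $d \in [0,1]$ with $d=1$ exactly at disjoint
supports, and $d$ is a metric (verified property-style in the tests). No
pseudocount is added: the mixture $m$ is positive wherever either profile
is, and $0\log 0 := 0$ is well defined, so a pseudocount would only add an
arbitrary constant.

Clustering is k-medoids. For tiny problems (at most 5000 candidate medoid
sets, e.g. any n ≤ 14 at k = 2) the optimum is found by exhaustively
enumerating medoid sets, ties broken towards the lowest sample indices; this
makes the small-sample behaviour exactly reproducible and lets the test
suite compare against an independent enumeration. At study scale the
standard deterministic BUILD+SWAP heuristic of `cluster::pam` is used — the
same algorithm the enterotype literature uses — which terminates when no
single swap lowers the total distance to assigned medoids. Neither route
consumes random numbers.

The number of clusters is selected over k ∈ {2, …, 10} by the
Calinski-Harabasz index; the mean silhouette width is reported alongside,
and a message flags any disagreement between the two (selection stays with
CH, which is the criterion the protocol designates). CH needs coordinates,
not distances, so it is evaluated on the classical-scaling (PCoA) embedding
retaining all positive-eigenvalue axes — the standard device for
distance-only data. k < 2 is undefined for both indices, which fixes the
interpretation of "cluster counts up to ten" as {2, …, 10}. In PCoA,
negative eigenvalues (JSD is metric but not Euclidean) are clamped to zero
and excluded from the explained-variance fractions; requesting more axes
than there are positive eigenvalues truncates with a warning.

When k = 2, the cluster with the higher mean *Bacteroides* relative
abundance is named ICU_E1 (falling back to `Enterobacteriaceae*` if
*Bacteroides* is absent), matching the taxonomy of the two ICU enterotypes;
naming by marker content rather than cluster index makes labels stable
across runs and cohorts.

## Biomarker selection

The screen operates on a multi-rank feature matrix: the table aggregated at
each rank phylum → genus, each rank block scaled per sample to sum 10⁶ (the
canonical scaling for LDA effect-size screening; it puts the later
log₁₀-effect gate on its conventional scale). Mixing ranks lets a phylum
and one of its genera both become markers; the later redundancy penalty
discourages but does not forbid that, which is the intended behaviour.

Stage one drops features failing a Kruskal-Wallis test at α = 0.05
(constant features have no rank information and are dropped here too).
Stage two scores survivors over 30 subsample rounds at 2/3 of each class
(classes below 2 members in a round are redrawn): per round, a one-axis
linear discriminant is fitted and the effect size of feature $f$ is
$\tfrac12(|w_f \cdot \Delta_{proj}| + |\Delta_f|)$ — half the sum of the
feature's share of the projected class-mean difference and its raw
class-mean difference. The reported score is $\log_{10}(\max(\text{effect},
1))$, averaged over rounds, and only features above the 2.0 gate are
retained. The discriminant direction is computed as a ridge-regularised
Fisher discriminant $w \propto (S_w + \lambda I)^{-1}(\mu_1 - \mu_2)$ with
$\lambda = 10^{-6}\,\overline{\text{diag}(S_w)}$: compositional multi-rank
features are exactly collinear (a family equals the sum of its genera), so
the pooled scatter is singular and a plain inverse does not exist; the
small ridge makes the direction well defined and deterministic without
materially changing it on well-conditioned data.

mRMR uses the mutual-information difference (MID) criterion of the original
formulation: the first pick maximizes I(f; class); each later pick
maximizes I(f; class) minus the mean MI with the already-selected set.
Features are discretized into 3 bins at mean ± 0.5 sd before any MI
computation (the original discretization; with zero variance everything
falls in the middle bin). Ties break towards higher relevance, then
lexicographic feature name, making selection fully deterministic.
Candidates are split by the enterotype they are enriched in before
selection, because the MHI formula needs exactly five markers per side;
five markers per enterotype is the protocol's choice.

## The MHI classifier

The score of a sample is
$\text{MHI} = (\sum_i \text{ABU}_r(S_i) + \varepsilon) / (\sum_j
\text{ABU}_r(S_j) + \varepsilon)$ with $\varepsilon = 10^{-6}$: a sample
lacking every denominator taxon must still receive a finite (large,
semantically E1) score, and a sample lacking all ten markers scores exactly
1, the uninformative midpoint. Markers missing from a table contribute zero
by contract — important for external cohorts.

Threshold training follows the grid sweep: 1001 candidate thresholds from
the training minimum to maximum in steps of (max − min)/1000; at each,
sensitivity (E1 positive, calls by score **strictly above** threshold) and
specificity are evaluated, and the threshold maximizing Youden's
J = sensitivity + specificity − 1 is chosen. "Locally optimal sensitivity
and specificity" is operationalized as the global maximum of J over the
fixed grid — deterministic, and identical to any sensible stopping rule on
separable data. Ties, including J values that are equal as rationals but
differ in floating point (8/12 + 8/12 versus 6/12 + 10/12), break towards
the smallest threshold via a 1e-12 tolerance. Training errors out on
single-class input or zero score range rather than guessing.

Evaluation uses an 80/20 split stratified by enterotype (plain random
splitting can produce single-class test sets at n = 131), the rank
(Mann-Whitney) AUC with half credit for ties, and a percentile 95% CI from
9999 class-stratified bootstrap resamples, deterministic given the seed.
F1, sensitivity and specificity take ICU_E1 as positive — the MHI is built
numerator-E1 — and the E2-positive F1 is also computed for reporting
symmetry. A frozen classifier (biomarkers + threshold) can be applied to an
external cohort; if more than five of the ten markers cannot be resolved
against the external taxonomy the classifier is declared non-transferable
rather than silently scoring near-empty ratios.

## Clinical associations

Fisher's exact test uses the point-probability two-sided convention (sum of
hypergeometric probabilities no larger than the observed table's), the
convention of R's `fisher.test` and the one consistent with the published
p-values on the reconstructed tables. Enterotype × outcome tables are
formed within APACHE II > 18 and ≤ 18 strata (the published severity
cutoff); lactate grouping puts the 2.5 mM boundary in the high group, uses
each patient's first sample, and excludes (with a count) records missing
lactate. Mann-Whitney tests enumerate exactly when n₁+n₂ ≤ 12 without
ties and otherwise use the tie-corrected normal approximation. The
correlation matrix is Pearson on z-scored parameters with pairwise-complete
observations (minimum 3 per pair; zero-variance columns flagged as NA).

The Mantel test correlates the lower triangles of the JSD matrix and the
absolute z-score differences of a clinical scalar — turning a scalar into a
distance matrix by |z_i − z_j| is the natural 1-d Euclidean choice. The
p-value is one-sided upper-tail, (count of permuted r ≥ observed + 1) /
(n_perm + 1), permuting one matrix's sample order; an exhaustive mode
evaluates all n! permutations for n ≤ 8 and anchors the sampled mode in the
tests. Repeated samples per patient are handled by the first-sample rule
throughout the association battery; the stratified shock test can also run
on all samples, mirroring the published per-sample table, in which case the
output should be read as repeated-measures. No multiple-testing correction
is applied across the battery, matching the protocol.

## The synthetic cohort generator

The generator emulates the study conditions: 131 samples from 64 patients
(1–5 samples each over 9 ICU days), patient-level enterotype prevalence
89:42, three driver taxa with log-normal relative-abundance gradients
(*Bacteroides* 0.206 vs 0.024, unclassified Enterobacteriaceae 0.251 vs
0.082, *Enterococcus* 0.010 vs 0.180 — the published cohort means), the
remaining mass filled by a Dirichlet draw over 29 background gut genera
(concentration 40 over uneven base weights), multinomial counts at a
log-normal sequencing depth (median 15k reads, occasionally under the
4000-read rarefaction depth so the dropping path is exercised), APACHE II
20.37 ± 8.14 and SOFA 10.67 ± 4.02 truncated at zero, per-enterotype
log-normal lactate targeting 2.66 ± 3.30 vs 1.42 ± 0.52 mM (floored at 0.1
mM), and septic-shock risk that differs between enterotypes only within the
high-APACHE stratum (0.40 vs 0.10 above the cutoff, 0.12 below) — the
planted form of the severity-conditional association.

Driver dispersions are not published; the printed ± values are standard
errors or standard deviations depending on the quantity and do not pin a
per-sample spread. The default sets each driver's sd to 0.4 of its mean
(log-normal cv 0.4), chosen so that the default cohort shows the clean
two-cluster structure the study reports — log driver distributions with
separated modes and a mean silhouette around 0.3 — while keeping
substantial within-enterotype spread. Setting the two enterotypes' driver
parameters equal (`equalize_enterotypes`) collapses clustering recovery to
chance, which is the negative control showing the signal lives in the
generator, not the algorithms.

What the generator does **not** emulate: taxon-taxon interactions beyond
compositional closure, day-to-day autocorrelation within a patient (samples
are exchangeable given the patient's enterotype), antibiotic
pharmacodynamics, and read-level artifacts (chimeras, OTU mis-assignment).
Passing recovery tests on these cohorts therefore demonstrates the
pipeline's correctness and sensitivity under a favourable, known-truth
model — not performance on real sequencing data.

## Problem sizes and determinism

The test suite runs the full recovery loop on 100 seeded cohorts of 131
samples, the null calibration on 200 seeded single-enterotype cohorts of 60
samples with 999 Mantel permutations, and the oracle equivalences on
exhaustive enumerations (all 2×2 tables with total ≤ 40, all medoid sets at
n ≤ 8, all 120 permutations at n = 5, all 1001 grid points). Bootstrap
replicates default to the protocol's 9999 but are parameters everywhere, so
the heavy loops in tests use smaller values where only the point estimate is
under test. Every stochastic stage derives its seed from the global seed
and the stage name (`stage_seed`), so toggling one stage never shifts
another's stream, and all results are bit-reproducible given the seed.

## Known limitations

- The published cohort-specific results (cluster sizes 89/42, threshold
  1.017, the cohort AUC/F1 table) require the deposited sequencing data and
  read-level processing that is out of scope; this package reproduces the
  protocol and validates it on synthetic ground truth.
- The LDA effect-size screen is a self-contained reimplementation of the
  LEfSe idea with its settings made explicit (α = 0.05, 30 rounds at 2/3,
  per-rank 10⁶ scaling, effect floor 1, gate 2.0); numbers from other LEfSe
  implementations will differ in detail.
- With heavily tied MHI scores the grid sweep can sit between tied
  thresholds; the smallest-threshold rule is a convention, not an optimum.
- CH on PCoA coordinates discards negative-eigenvalue axes; for distance
  matrices far from Euclidean the discarded mass could matter (JSD at this
  scale is nearly Euclidean and loses little).
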
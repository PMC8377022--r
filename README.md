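# mhindex

Enterotype analysis of ICU gut microbiota and the **microbial-based human
index (MHI)** — a single-sample score for calling which of the two ICU
enterotypes a septic patient's gut community belongs to.

## The problem

The gut microbiota of intensive-care patients with sepsis or septic shock is
severely dysbiotic, but the dysbiosis is not formless: unsupervised
clustering of genus-level community profiles reveals two recurring
configurations ("ICU enterotypes"). ICU E1 is dominated by *Bacteroides*
together with an unclassified Enterobacteriaceae genus; ICU E2 is dominated
by *Enterococcus*. The two configurations associate differently with
clinical outcome — septic shock among high-severity patients and elevated
serum lactate both track E1 — so knowing a patient's enterotype from a
single stool sample is clinically useful. This package implements the whole
analysis chain for anyone who has a taxonomic relative-abundance table and
per-sample clinical metadata: microbiome bioinformaticians reproducing the
protocol on their own ICU cohorts, and methodologists who want each stage as
a tested, reusable function.

## The method

1. **Enterotype discovery.** Pairwise Jensen-Shannon distances
   d(x, y) = √JSD(x, y) (log base 2, so d ∈ [0, 1]) between genus-level
   profiles; partitioning-around-medoids clustering; the number of clusters
   k ∈ {2, …, 10} chosen by the Calinski–Harabasz index
   CH = [B/(k−1)] / [W/(n−k)], with the mean silhouette width s(i) =
   (b−a)/max(a, b) reported alongside; PCoA for visualization.
2. **Biomarker selection.** An LDA effect-size screen (Kruskal–Wallis at
   α = 0.05, then a bootstrapped one-axis linear discriminant on per-rank
   abundances scaled to 10⁶) retains taxa with Log₁₀ LDA score > 2.0;
   greedy mRMR (mutual-information difference criterion) then picks five
   non-redundant markers per enterotype across ranks phylum–genus.
3. **The MHI classifier.** For a sample with relative abundances ABUᵣ,

   MHI = Σᵢ ABUᵣ(Sᵢ) / Σⱼ ABUᵣ(Sⱼ),

   numerator over the five E1 markers Sᵢ, denominator over the five E2
   markers Sⱼ. The decision threshold is trained on an 80/20 stratified
   split by sweeping 1000 steps from the minimum to the maximum training
   score and maximizing Youden's J; scores above the threshold call ICU E1.
   Performance is reported as ROC AUC with a 95% CI from 9999 stratified
   bootstrap replicates, F1, sensitivity and specificity, and a frozen
   classifier can be applied to external cohorts.
4. **Clinical associations.** Fisher's exact tests of enterotype against
   septic shock within APACHE II strata (cutoff 18) and against lactate
   groups (cutoff 2.5 mM), Mann–Whitney comparisons, a Pearson correlation
   matrix of z-scored clinical parameters, and Mantel tests of the JSD
   matrix against clinical parameters.
5. **Synthetic cohorts.** A generator with known ground truth (log-normal
   driver taxa over a Dirichlet-multinomial background, enterotype-
   conditional clinical covariates) so the whole chain is testable without
   any sequencing data.

## Worked example

```r
library(mhindex)

coh <- generate_cohort(cohort_config(), seed = 42)   # 131 samples, 64 patients
cfg <- pipeline_config(seed = 42, n_boot = 999)
res <- run_full_pipeline(coh$abundance, coh$metadata, cfg)
print(res)
```

```
Enterotype partition (JSD + PAM)
  samples: 131   k: 2 (CH = 65.11, mean silhouette = 0.292)

ICU_E1 ICU_E2 
    71     60 

Biomarker set (LDA effect size + mRMR)
   ICU_E1 (numerator): g__Bacteroides, f__Enterobacteriaceae, c__Bacteroidia, f__Bacteroidaceae, g__Enterobacteriaceae* 
   ICU_E2 (denominator): f__Enterococcaceae, f__Streptococcaceae, p__Firmicutes, g__Enterococcus, c__Bacilli 

      set   n   auc ci_low ci_high     f1 sensitivity specificity
 training 105 1.000 1.0000       1 1.0000           1      1.0000
  testing  26 0.994 0.9643       1 0.9655           1      0.9167

APACHE>18 stratum Fisher p = 0.06268; lactate-group Fisher p = 0.4983
```

Reading the output: the JSD/PAM stage found two clusters (k chosen by CH
over 2–10); the biomarker stage selected the three planted driver taxa
(`g__Bacteroides`, `g__Enterobacteriaceae*`, `g__Enterococcus`) plus their
most informative higher ranks; the MHI threshold trained on 105 samples
separates the held-out 26 samples almost perfectly (AUC 0.994). The
association p-values refer to this particular simulated cohort — a single
draw of 131 samples, so the planted severity-conditional shock effect is
not always significant at n = 131, exactly as in a real cohort of this
size. A rank-prefixed name with a trailing `*` (e.g.
`g__Enterobacteriaceae*`) denotes a genus-level group classified only to a
higher rank.

A command-line front end over the same functions lives in
`inst/cli/mhindex.R` (subcommands `simulate`, `enterotype`, `biomarkers`,
`mhi-train`, `mhi-classify`, `assoc`, `run-all`).

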
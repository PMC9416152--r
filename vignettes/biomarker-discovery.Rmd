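---
title: "Predicting microbial taxon presence from soil metabolite profiles"
author: "otumarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting microbial taxon presence from soil metabolite profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

`otumarker` implements a correlation-free route from paired soil omics blocks
— a 16S rRNA OTU count table and a GC–MS exometabolite abundance matrix,
collected on the same samples under three moisture regimes (Dry-Wet, Wet-Dry,
continuous Saturation) — to a ranked list of *biomarker metabolites*:
metabolites whose abundance profile predicts whether individual microbial
taxa are present in a sample.

The core statistical object is a per-OTU binary classifier. Within one
moisture treatment, each OTU's counts are binarized (present ⇔ nonzero
count), and a random forest is fit with the normalized log2 metabolite
abundances as predictors. The forest's bootstrap aggregation provides
internal validation: every sample is out-of-bag (OOB) for roughly
`exp(-1) ≈ 37%` of trees, and the majority vote of those trees yields an
honest prediction for it. Model quality is summarized as **balanced
accuracy** — the mean of the true-positive and true-negative rates — which
is insensitive to the presence/absence imbalance that is ubiquitous in
sparse OTU tables. Models with OOB balanced accuracy at or above 0.80 are
retained; within the retained set, every (metabolite, model)
mean-decrease-Gini importance score is pooled, and scores in the top 20%
of that pool define the strong metabolite→OTU predictor pairs.

## Preprocessing

Both blocks pass through the conventional preprocessing of this data type:

* **OTU block** — OTUs observed in fewer than 2 samples are removed; a
  randomization test on mean pairwise Jaccard distances screens for outlier
  samples; counts are upper-quartile normalized (each sample divided by the
  75th percentile of its nonzero counts, then rescaled by the mean of those
  percentiles so values stay count-like). Treatment-pair shifts in relative
  abundance are screened with Welch *t* tests on log2 values (half-minimum
  pseudocount) and Benjamini–Hochberg correction across the full OTU × pair
  family, significant at adjusted *p* < 0.05.
* **Metabolite block, univariate branch** — metabolites observed in at least
  2 samples in at least 2 of the 3 treatments are kept; values are log2
  transformed and median-centered per sample (missing entries retained).
  Each metabolite is tested with a REML linear mixed model: moisture
  treatment as the fixed effect and soil core as a random intercept, since
  technical replicates are repeated measures of the same core. All three
  pairwise contrasts receive a single-step (max-*t*) adjustment; Bonferroni
  is available as a fallback.
* **Metabolite block, classification branch** — log2 transform, then
  half-minimum imputation (every missing cell set to half the smallest
  observed log2 abundance in the whole matrix — a detection-limit
  interpretation of missingness), then per-sample median centering.
  Forests require complete predictors, which is why imputation precedes
  centering on this branch.

The two branches deliberately differ: the mixed model tolerates (and should
see) genuine missingness, while the classifier needs complete data.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_otu_samples` | 2 | rare-OTU filter floor (samples with nonzero count) |
| `outlier_permutations`, `outlier_alpha` | 999, 0.05 | randomization-test resolution and level (Bonferroni-adjusted) |
| `min_present`, `min_absent` | 3, 3 | per-treatment eligibility floors for classification |
| `balanced_accuracy_threshold` | 0.80 | OOB gate for retaining a model |
| `importance_top_fraction` | 0.20 | pooled-importance fraction defining strong pairs |
| `n_trees`, `mtry`, `min_node_size` | 500, ⌊√p⌋, 1 | forest defaults, following the classical classification settings |

Quantiles everywhere use the linear-interpolation convention
(`stats::quantile`, type 7); "75th quartile" is ambiguous across software,
so the convention is fixed and recorded in `processing_params()`.

## The random forest

The forest is implemented in compiled code inside the package (trees grown
by recursive Gini-impurity splitting on midpoint thresholds, `mtry`
predictors sampled per node, full-size bootstrap bags, OOB vote
accumulation, and mean-decrease-Gini bookkeeping per node). Three behaviors
are fixed for reproducibility:

* ties in split quality break toward the lowest predictor ID, then the
  lowest threshold; zero-gain splits are inadmissible;
* predictors are canonicalized by name before training, so results are
  invariant to column order;
* a single master seed derives an independent deterministic stream per tree,
  and each OTU's forest is seeded by a hash of the master seed and the OTU
  ID, so adding or removing OTUs never perturbs other models. OOB vote ties
  break toward "present" (configurable); the gate treats the classes
  symmetrically, so the choice is not consequential for retention.

An established ensemble implementation (`randomForest`, in Suggests) serves
as an independent cross-check in the test suite — agreement is
distributional (OOB error, top-importance recovery), never bit-wise.

## The synthetic study generator

Because the underlying field study's raw data are not deposited, the package
ships a generator that emulates the study's structure and plants known
metabolite→OTU links, so that every downstream stage is testable end to end:

* 41 samples split 10 (D-W) / 18 (W-D) / 13 (Sat), nested in soil cores,
  with technical replicates sharing their core's random intercept;
* metabolite log2 abundances = baseline + per-metabolite treatment shift
  (SD 0.5) + core intercept (SD 0.25) + residual (SD 1); the residual
  dominates by design, because treatment- and core-level offsets are exactly
  what per-treatment modelling and per-sample normalization remove;
* missingness is detection-limit censoring by default (low abundances drop
  out first through a soft logistic boundary), matching how GC–MS data lose
  observations and why half-minimum imputation is sensible for them; a
  value-independent (`"mcar"`) mechanism is available for comparison;
* target OTUs are present with probability
  `plogis(intercept + slope · z)`, where `z` is the driver metabolite's
  latent log2 abundance *median-centered within the sample's profile* and
  standardized within the treatment, and `|slope| = effect_size`. The link
  acts on relative abundance — the scale the classifiers actually see.
  Planting on absolute abundance instead buries part of the association in
  sample-level offsets that median centering removes, capping recoverable
  accuracy regardless of slope;
* each target depends on a single driver drawn from a small driver pool.
  This is a deliberate choice: at the study's dimensions (tens of samples,
  ~100 metabolites) additive multi-driver rules are statistically
  unrecoverable by any forest — a fact we verified with the reference
  implementation on noiseless labels — so multi-driver targets would test
  sample-size limits, not the pipeline;
* present entries receive counts `1 + NegBin`, so presence always means a
  nonzero count; a small dropout rate (2%) then zeroes some present entries,
  emulating sequencing dropout;
* non-target OTUs are independently present with uniform prevalences; target
  intercepts are drawn from the classifiable prevalence band (0.3–0.7).

What the generator does **not** emulate: compositionality constraints of
real sequencing depth, taxon–taxon ecological dependence, metabolite–
metabolite correlation structure, and batch effects. Passing recovery tests
on this generator therefore demonstrates that the pipeline's machinery is
correct and calibrated, not that real soil data contain recoverable signal
of any particular strength.

A note on effect sizes: with a logistic link on a Gaussian predictor, label
noise decays only like ~0.55/slope, so even slopes of 6–8 leave ~7–9%
irreducible label noise — enough to hold OOB balanced accuracy below a 0.80
gate at n = 40. Recovery studies therefore use slopes in the
near-deterministic regime (≥ 12) when the question is whether the pipeline
finds planted structure. At the study's own scale (10–18 samples per
treatment) even strong links rarely clear the gate — the mechanism behind
an empty biomarker list for a small treatment arm, which the null study
reproduces.

## Numerical and design choices

* Processing order for the classification branch is log2 → impute → center;
  the univariate branch is log2 → filter → center with missingness kept.
* The outlier statistic is the mean Jaccard distance to all other samples;
  the null permutes each OTU column independently (preserving per-OTU
  prevalence); p-values are one-sided with the +1 correction and
  Bonferroni-adjusted across samples. The test canonicalizes sample order
  internally, so results do not depend on input row order.
* "Across all models" for the top-20% importance pool is interpreted
  per treatment (the two reported treatments are ranked separately);
  `pooling_scope = "global"` computes the alternative. The gate is applied
  before pooling; `gate_first = FALSE` computes the other order.
* Importance scores are pooled raw (no per-model rank normalization) —
  mean decrease in Gini is comparable across models sharing one predictor
  set.
* The manifest records seeds, configs, and per-stage counts, and contains
  no wall-clock fields, so identical master seeds reproduce results byte
  for byte.
* Degenerate inputs fail loudly: all-zero samples in normalization, samples
  with no observed metabolites in centering, single-class outcomes in the
  forest, and single-treatment designs in the mixed model are all errors
  naming the offender.

## Problem sizes used in the test suite

Unit tests run on small fixtures (tens of samples, tens of features).
Recovery and calibration studies use 40 samples per treatment, 100
metabolites, 30 OTUs (10 targets, 5-driver pool) over 20 fixed seeds —
dimensions at which the gate's behavior is statistically meaningful while a
full run stays comfortably interactive. The mixed-model recovery study uses
198 samples across 33 cores and 100 seeds.

## Known limitations

* The per-OTU forests ignore the core nesting within treatments (replicates
  enter as independent samples, matching the original analysis's sample
  accounting); OOB estimates can be slightly optimistic when core effects
  are strong. The manifest surfaces the caveat.
* The treatment-pair abundance screen for OTUs is a pipeline-completeness step; the
  choice of Welch *t* on log-normalized counts (Wilcoxon as alternative) is
  a documented convention, not an inference claim.
* Balanced accuracy on 10–18 samples is coarse-grained; gate decisions at
  that scale carry substantial sampling noise.
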
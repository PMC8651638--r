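# endotypr

Unsupervised discovery and validation of RNA-defined patient subgroups
(endophenotypes) in whole-blood transcriptomes of idiopathic/heritable
pulmonary arterial hypertension (I/HPAH) cohorts.

Patients with the same haemodynamic diagnosis differ several-fold in
survival. `endotypr` partitions patients by bulk RNA-seq expression
alone and then interrogates the subgroups against everything else that
is known about the patients: survival, clinical variables, genotype
frequencies and qPCR measurements. The core machinery is:

* **Preprocessing** — transcript→gene TPM aggregation, a >2-abundance
  in ≥95%-of-samples expression filter, sex-chromosome gene removal,
  and the hyperbolic arcsine transform
  `asinh(x) = log(x + sqrt(x^2 + 1))`.
* **Stability-selected spectral clustering** — genes ranked by
  variance; candidate gene-set sizes judged by bootstrap cluster
  stability (mean Jaccard overlap between original and resampled
  clusters); RBF affinity `A_ij = exp(-σ‖x_i−x_j‖²)`; symmetric
  normalised Laplacian embedding + k-means; the number of subgroups
  `k` voted by an ensemble of internal validity indexes (silhouette,
  Calinski–Harabasz, Davies–Bouldin, Dunn, connectivity,
  within/between SS, PBM, C-index); algorithm choice justified by
  partitional consistency (mean pairwise adjusted Rand index across
  algorithm variations).
* **Signatures** — per-subgroup gene signatures by one-vs-rest
  cross-validated LASSO with top-5% highlighting and Bonferroni-adjusted
  fold changes; clinical signatures by three-selector ensemble feature
  ranking and a size-1..20 search over SVM/RF/LR/kNN classifiers.
* **Transfer classification** — pooled composite clinical signature,
  multi-class linear SVM, frozen training scaling, applied to an
  independent clinical-only cohort.
* **Survival & association validation** — Kaplan–Meier, log-rank, Cox
  (Efron ties), two-proportion and Fisher exact tests, a bipartite
  gene–clinical Spearman network thresholded at |rho| ≥ 0.25 and
  p < 1.11×10⁻⁵, and ΔΔCt qPCR arithmetic (RQ = 2^−ΔΔCt against a
  GAPDH-like reference).
* **Synthetic cohort generator** — real cohorts of this kind sit under
  restricted access, so `generate_cohort()` draws cohorts with the
  statistical structure such studies exhibit (marker-gene blocks ordered
  low/intermediate/high across prognosis groups, subgroup-specific
  exponential hazards calibrated to 53%/65%/78% five-year survival,
  shifted clinical features, genotype frequency differences, MCAR/MAR
  missingness) plus full ground truth, so the entire pipeline is
  testable offline.

## Worked example

```r
library(endotypr)

spec   <- cohort_spec(seed = 5)          # the default study conditions
cohort <- generate_cohort(spec)
valid  <- generate_validation_cohort(spec)

res <- run_pipeline(cohort, valid, pipeline_config(seed = 5),
                    out_dir = "run1")

res$vote$majority_k
#> [1] 3
res$manifest$chosen_geneset_size
#> [1] 300
adjusted_rand_index(res$partition, cohort$truth$labels)
#> [1] 1
round(res$composite$cv_balanced_accuracy, 3)
#> [1] 0.827
signif(res$survival$validation_logrank$p, 3)
#> [1] 2.56e-08
```

Reading: the index ensemble votes three subgroups; the 300 most
variable genes form the most bootstrap-stable clustering substrate; the
spectral partition recovers the planted subgroups exactly (adjusted
Rand index 1); a composite clinical signature classifies patients with
~83% CV balanced accuracy; and when that classifier labels the
independent 197-patient validation cohort, the predicted subgroups'
Kaplan–Meier curves separate decisively (log-rank p ≈ 3×10⁻⁸) in the
planted order poor < moderate < good. The fitted Cox model sees the
poor subgroup as the dominant risk factor among age/sex covariates.

A thin command-line wrapper lives at `inst/cli/endotypr`
(subcommands `simulate`, `run`, `discover`, `survive`).

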
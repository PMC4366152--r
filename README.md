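# dhgs — genomic selection and flowering-time locus mapping in doubled-haploid populations

`dhgs` is an R package for breeders and quantitative geneticists working
with biparental doubled-haploid (DH) panels — the setting of
flowering-time (FT) studies in oilseed rape (*Brassica napus*), where a
Tapidor × Ningyou7-style cross is genotyped at ~1,700 SNPs and phenotyped
across ten site–year environments in three geographic regions. It covers
the full chain from raw genotype calls to annotated candidate loci:

* **Quality control and LD pruning** — the classical cascade (samples
  with ≥ 20% missing calls, markers missing in > 10% of samples, MAF
  < 0.05), −1/+1 coding with mean imputation, and greedy map-ordered
  pruning into tag-SNP clusters at r² < 0.7.
* **Eight whole-genome prediction models** under one fit/predict
  contract: RR-BLUP (exact ridge with REML-selected penalty), Bayesian
  LASSO, BayesA and BayesB (Gibbs samplers in C++), Gaussian-kernel RKHS
  regression, ε-insensitive SVR with linear and Gaussian kernels, and
  random forests. The linear model is
  `y_i = mu + sum_j beta_j x_ij + e_i` with `x_ij ∈ {-1, +1}`; the
  families differ only in how the `beta_j` are shrunk.
* **Repeated 10×10-fold cross-validation** with fold plans shared across
  models (hash-checked), Pearson-correlation accuracy, and
  model-comparison tables.
* **Breeding values** — overall GEBVs (site–year covariates) and
  per-region EBVs (year covariate) by kernel BLUP.
* **Associated-SNP selection** — tag SNPs ranked by permutation
  importance averaged over 20 forests, recursive 5%-step inclusion to
  the minimal-OOB-MSE set, expansion to the represented SNPs, and
  allelic-direction consistency by Welch's t-test per environment.
* **Epistasis mapping** — degree-2 MARS on the selected tags with
  GCV pruning and 10×10-fold stability selection of marker×marker pairs,
  plus cross-region replication tables.
* **Functional enrichment** — ±1 kb SNP→gene window mapping,
  hypergeometric (Fisher) fold-enrichment per term, and cluster
  enrichment scores with the 1.3 (p = 0.05) threshold.
* **A DH-population simulator** — doubled gametes under the Haldane map
  function, map-driven LD, multi-environment phenotypes with G×E and a
  target heritability, planted additive QTLs and epistatic pairs, and
  patterned missingness, for calibration and recovery testing.

## Worked example

```r
library(dhgs)

sim   <- simulate_dh_panel(seed = 42)   # 190 lines x 1,674 markers, 10 envs
panel <- qc_filter(sim$geno)
panel
#> <genotype_panel> 182 lines x 1256 markers after QC
#>   (removed: sample_missingness=8, marker_missingness=418, maf=0)

clustering <- ld_prune(panel$coded, sim$map)
clustering
#> <tag_clustering> 1256 markers in 190 clusters

pheno <- sim$pheno[sim$pheno$line_id %in% rownames(panel$coded), ]
plan  <- make_folds(rownames(panel$coded), k = 10, repeats = 2, seed = 1)
cv <- lapply(list(model_spec("rr_blup"), model_spec("rkhs")),
             cross_validate, panel = panel, pheno = pheno, plan = plan,
             environments = c("N3", "S4"))
compare_models(cv)
#>       env  rkhs rr_blup
#> 1      N3 0.695   0.672
#> 2      S4 0.718   0.717
#> 3 Average 0.706   0.694

gebv <- estimate_gebv(panel, pheno, scope = "overall")
cor(gebv$gebv, sim$truth$genetic_value[gebv$line_id])
#> [1] 0.9700769
```

Eight lines were dropped by the sample-missingness rule and 418 markers
by the marker rules, leaving the 182 × 1,256 panel the models see. The
cross-validated accuracies (~0.67–0.72) are Pearson correlations between
observed and out-of-fold predicted FT within an environment — close to
the `sqrt(h2) ≈ 0.77` ceiling of the simulated h² = 0.6 panel — and the
GEBVs recover the simulated genetic values at r = 0.97.

Downstream, `estimate_gebv(..., scope = "per_region")` feeds
`rank_importance()` → `recursive_inclusion()` → `expand_tags()` for
associated-SNP selection, `allele_direction()` for early-allele
consistency, `select_interactions()` for epistatic pairs, and
`snps_to_genes()` / `term_enrichment()` / `significant_clusters()` for
annotation, as shown in `scripts/acceptance.R`.

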
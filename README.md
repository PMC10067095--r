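# evsubtype

Two-stage analysis of targeted (SRM-style) plasma extracellular-vesicle
proteomics cohorts:

1. **Candidate screening** on a discovery cohort (healthy controls plus
   early- and late-stage patients): per-feature Mann–Whitney–Wilcoxon
   comparisons at a raw α = 0.05 (exact enumeration for small groups,
   tie-corrected normal approximation otherwise), combined with
   importance rankings from unsupervised random forests (Breiman's
   real-vs-synthetic contrast), assembled into a provenance-tracked
   candidate list.
2. **Prognostic subtyping** on an independent patient cohort:
   half-minimum imputation of below-detection-limit (MNAR) values,
   Monti-style resampling consensus clustering with the number of
   clusters k chosen by minimizing the PAC
   (proportion of ambiguous clustering,
   PAC = CDF(0.9) − CDF(0.1) of the consensus indices), then subtype
   characterization: Kaplan–Meier / log-rank survival comparison,
   volcano marker discovery (fold change > 2, p < 0.05), per-marker
   median-split survival, multivariate Cox regression (Efron ties),
   Fisher's exact test on curative resection, and the positive
   protein–protein Pearson(log2) correlation network at
   Benjamini–Hochberg FDR < 1e-4.

The package also ships a synthetic-cohort generator with known ground
truth (planted subtypes, elevated proteins, hazard ratio,
detection-limit censoring), used throughout the test suite for
parameter-recovery validation.

## Worked example

Simulate a 110-patient subtyping cohort (99 proteins, 12 of them
elevated 2.5-fold in a 40% minority subtype that carries a 2.5 hazard
ratio, ~10% MNAR missingness) and run the full stage-2 pipeline:

```r
library(evsubtype)

params <- simulation_params(seed = 5)
cohort <- generate_cohort(params, "cohort2")

cfg <- pipeline_config(quantification_limit = 0,  # generator already censored
                       n_resamples = 250, seed = 5)
res <- run_pipeline(cfg, list(cohort2_abundance = cohort$abundance,
                              cohort2_annotation = cohort$annotation))
res
#> evsubtype run
#>   99 proteins x 110 samples; chosen k = 2 (PAC 0.000)
#>   cluster sizes: 66/44
#>   log-rank between clusters: chisq = 25.90, p = 3.599e-07
#>   volcano: 0 up, 12 down; network edges (FDR < 0.0001): 66
```

The planted structure is recovered exactly — note that final cluster
labels are ordered by decreasing size, so the 44-patient minority
subtype is cluster 2 and the planted markers show up as *down* in
cluster 1 (equivalently, up in cluster 2):

```r
adjusted_rand_index(res$labels, cohort$truth$subtype_label)
#> [1] 1

head(subset(res$volcano, flag != "ns"), 3)
#>   protein        fc   log2_fc            p flag
#> 1    P001 0.3701125 -1.433964 1.774181e-18 down
#> 2    P002 0.3541991 -1.497367 3.119854e-20 down
#> 3    P003 0.3896159 -1.359876 1.284952e-17 down
```

The 66 network edges at FDR < 1e-4 are exactly the
`choose(12, 2) = 66` pairs of the planted co-regulated block.

Adding `cohort1_abundance` / `cohort1_annotation` to the `inputs` list
enables the stage-1 screen; `outdir =` writes all result tables (TSV)
plus a machine-readable `summary.json`. A thin command-line front end
with `simulate` / `screen` / `cluster` / `survival` / `network` /
`all` subcommands is installed at `inst/cli/evsubtype.R`.

## Documentation

The methods vignette
(`vignettes/two-stage-ev-subtyping.Rmd`) documents the statistical
model of each stage, the defaults and their rationale, what the
synthetic generator does and does not emulate, and the numerical
design decisions (cluster-size label ordering, strict volcano
thresholds compared at 12 significant digits, uniform-censoring
calibration, PAC tie-breaking toward small k).
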
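# thymoflow

Computational flow cytometry for developing thymocytes: an R implementation
of the pooled, graph-based analysis strategy that single-cell
transcriptomics brought to cytometry, aimed at immunologists who need to
track thymocyte population frequencies across many donors and acquisition
days without drawing per-sample gate trees.

The pipeline: read FCS 3.0/3.1 → compensate spillover
(`x_true = x_obs S⁻¹`) → logicle (biexponential) transform → declarative
exclusion gating (singlets, debris, lineage dump) → pool all samples of a
panel and z-score retained markers → subsample by a stratified random draw
plus a geometric sketch (grid-cover sampling that enriches rare
populations) → regress acquisition-day batch effects out of each marker
(OLS residuals) → fuzzy k-nearest-neighbour graph → iterative Leiden
clustering maximising `Q(γ) = Σ_c (e_c − γ K_c²/2m)` → annotate clusters
from scaled median-fluorescence profiles (or transfer labels across
developmental branches with ridge logistic regression) → per-sample
population frequencies, F-measure benchmarking against reference gates,
and age-group tests (`frequency ~ group + batch`, BH-adjusted q-values).

A synthetic-cytometry generator (`build_default_thymus_spec()`) plants
ground truth for all of it: five thymocyte staining panels, 26 MNC + 35
CD34-enriched samples spanning birth to 14 years, acquisition-day batches,
doublets/debris, spillover, a 0.2% plasmacytoid-DC population, and a
+0.02 B-cell frequency step after 1.5 years of age.

## Worked example

Simulate the B-cell/DC panel cohort, run the full pipeline, and test for
the age effect:

```r
library(thymoflow)

cfg <- pipeline_config(panel = "bdc", events_per_sample = 2000,
                       n_random = 6000, n_sketch = 6000,
                       master_seed = 42, out_dir = "bdc_run")
man <- run_pipeline(cfg)

read.delim("bdc_run/group_tests.tsv")
#>             population estimate p_value q_value
#> 1              B cells  0.02728 0.00202 0.00404
#> 2            cDC/macro  0.00101 0.59252 0.66074
#> 3                  pDC -0.00053 0.66074 0.66074
#> 4 T-lineage thymocytes -0.02777 0.00200 0.00404

aggregate(F ~ population, read.delim("bdc_run/f_measures.tsv"), median)
#>             population F
#> 1              B cells 1
#> 2            cDC/macro 1
#> 3                  pDC 1
#> 4 T-lineage thymocytes 1
```

Reading the output: every planted population — including the 0.2% pDC,
recovered thanks to the sketch — is identified with a median per-sample
F-measure of 1 against the planted truth, and the regression detects the
planted post-1.5-year B-cell step (+0.027 estimated vs +0.02 planted plus
donor jitter; q < 0.05) while correctly finding no age effect in the
myeloid populations. `bdc_run/` also contains the cluster assignments and
lineages, scaled-MFI cluster profiles, per-sample frequency table,
loess trend table and a JSON run manifest; re-running with the same master
seed reproduces all of them byte for byte.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/thymoflow.R simulate --panel cd34 --out fcs_dir --seed 1
Rscript inst/cli/thymoflow.R run --panel ab --out ab_run --seed 1
```

## Repository layout

- `R/` — implementation: synthetic generator, FCS I/O, logicle,
  compensation/gating/pooling, subsampling, batch correction, KNN/Leiden/
  UMAP/profiles, annotation/transfer, statistics, pipeline orchestration.
- `tests/testthat/` — unit, property and end-to-end acceptance tests; all
  fixtures are generated in code.
- `vignettes/computational-cytometry.Rmd` — the methods vignette: models,
  assumptions, parameter choices, what the synthetic cohort does and does
  not emulate, numerical choices, limitations.
- `inst/cli/thymoflow.R` — command-line front end.
- `scripts/acceptance.R` — see above.
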
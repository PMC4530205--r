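# dnacig

DNA/cytoplasmic-immunoglobulin (DNA/CIg) flow-cytometry indices and the
12-probe expression risk score (GEP12) for multiple myeloma, as a tested,
reusable R pipeline.

## The problem

Two-colour flow cytometry of nuclear DNA content and cytoplasmic
immunoglobulin light chains is a fast, antigen-independent way to
characterise the malignant plasma-cell compartment of a myeloma marrow.
From event-level kappa- and lambda-tube data the assay yields, per
specimen:

* the involved light chain and the **light-chain-restricted (LCR)**
  percentage of gated events;
* one or more **DNA stem lines** (discrete LCR subpopulations with
  distinct DNA content), each with a **DNA index**
  `DI = mean(LCR G0/1 peak) / mean(LC-negative diploid G0/1 peak)` —
  diploid for DI in [0.99, 1.01], hyperdiploid above, hypodiploid below —
  the dominant (largest) line setting the specimen's ploidy class;
* the **cytoplasmic immunoglobulin index**
  `CIg = geomean(LC-positive G0/1 light chain) / geomean(LC-negative diploid G0/1 light chain)`
  per stem line.  A specimen with any stem-line CIg below 2.8 is
  **low CIg**, an adverse prognostic state.

Because many cohorts lack DNA/CIg data, a gene-expression surrogate was
derived: 12 Affymetrix probe sets (11 genes) differ between low- and
high-CIg disease (Wilcoxon rank sum with permutation FDR; p < 1e-4,
q < 0.10), 3 over-expressed in low CIg (SLC19A1, BCCIP, CEP164) and 9
under-expressed.  On log2 expression,

```
GEP12 = (sum of the 9 under-expressed probes - sum of the 3 over-expressed probes) / 12
```

with scores strictly below 5.35 (a running log-rank optimal cutpoint)
defining the high-risk group.  Transfer to a second cohort uses a
reference-anchored ComBat transform that maps the target onto the
defining cohort's per-probe scale while leaving the reference
bit-identical.

The package implements all of it — flow analysis, signature derivation,
scoring, cutpoint selection, cohort transfer, and the survival and
association statistics used to evaluate the result — plus seeded
generators for synthetic specimens and cohorts with the statistical
structure the methods assume, so everything is testable without
patient-level data.

## Worked example

```r
library(dnacig)

## 1. Flow: a specimen with a diploid line (CIg 1.5) and a
##    hyperdiploid line (CIg 4.0), LCR 40%
params <- flow_sim_params(
  n_events = 10000,
  stem_lines = list(list(di = 1.00, fraction = 0.625, cig = 1.5),
                    list(di = 1.10, fraction = 0.375, cig = 4.0)),
  involved_chain = "kappa", lcr_fraction = 0.4, seed = 61)
tubes <- gen_flow_tubes(params)
build_profile(tubes$kappa, tubes$lambda)
#> DNA/CIg profile
#>   involved chain : kappa
#>   LCR%           : 40.2
#>   ploidy         : diploid (dominant DI 1.000)
#>   stem lines     : 2
#>     DI 1.000   18.8% of gated  CIg 1.52  [dominant]
#>     DI 1.100   11.4% of gated  CIg 3.88
#>   any CIg < 2.8  : TRUE
```

The analyser recovers the simulated DI within ±0.01, CIg within ±5% and
LCR% within ±2 points, and flags the specimen as low CIg.

```r
## 2. Score the published group-mean profiles with the packaged signature
tab <- cig12_probes()
sig <- cig12_signature()
gep12_score(setNames(tab$mean_low_cig,  tab$probe_id), sig)   # 5.49745
gep12_score(setNames(tab$mean_high_cig, tab$probe_id), sig)   # 6.168056
```

The low-CIg mean profile scores below the high-CIg one, consistent with
"< 5.35" marking the adverse tail.

```r
## 3. Covariate associations with low CIg from the packaged 2x2 counts
head(low_cig_assoc_odds_ratios(), 2)
#>       factor       or    ci_lo    ci_hi            p or_printed ci_lo_printed ci_hi_printed
#> 1 b2m_ge_3.5 3.390977 1.608220 7.149972 0.0013350265       3.39          1.61          7.15
#> 2 b2m_gt_5.5 3.982222 1.857727 8.536286 0.0003822083       3.98          1.86          8.54
```

Every recomputed odds ratio and Wald 95% CI matches the published table
at 2-decimal rounding.

```r
## 4. End to end on a synthetic cohort
cfg <- pipeline_config(seed = 20260901,
                       cohort = cohort_sim_params(n_patients = 60,
                                                  n_probes = 150,
                                                  noise_sd = 0.35,
                                                  censor_horizon = 240),
                       flow_n_events = 3000, n_perm = 100)
res <- run_pipeline(cfg, out_dir = "run1")
```

`run1/` then holds the per-stage outputs: flow profiles, probe-level
test results, the selected signature (JSON), per-sample scores with
risk flags, the cutpoint scan trace and a short report.  Re-running
with the same configuration reproduces them byte for byte.

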
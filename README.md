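# spinedecline

Yearly decline rates of lumbar spinal-column degeneration and
paravertebral-muscle quality, estimated from published age-aggregated
imaging summaries of asymptomatic adults.

Imaging studies report spinal ageing almost only in aggregate: per age
decade, the prevalence of a degenerative feature, or the mean ± SD of a
muscle's fat-infiltration percentage (FI%). `spinedecline` turns those
aggregates back into analysable data and puts every endpoint on a common
scale — percentage points of decline per year of adult life, with a 95%
confidence interval — so that the spinal column (disks, facets,
listhesis) and the paravertebral muscles (multifidus MF, erector spinae
ES, psoas) can be compared directly.

Two reconstruction models drive the package:

* **Prevalence tables** (8 spinal-column endpoints): each age group's
  `n` and prevalence π are expanded deterministically into
  `round(nπ)` ones and the rest zeros at the group's representative age.
  A logistic regression of outcome on age then yields the **average
  marginal effect** of a one-year age increase,

  `AME = (100/n) Σᵢ β̂₁ p̂ᵢ(1−p̂ᵢ)`  (%/year),

  with a delta-method standard error over the full coefficient
  covariance and CI `AME ± 1.96·se`.

* **Continuous tables** (7 muscle FI% endpoints): each iteration of a
  seeded **Monte Carlo simulation** (default 10,000 iterations) draws
  `nⱼ` normal variates per group from the published `N(μⱼ, σⱼ)`, fits
  ordinary least squares of FI% on age, and records the slope `b` and
  `se(b)`; the estimate is `mean(b)` with CI
  `mean(b) ± 1.96·mean(se(b))`.

A likelihood-ratio test of the linear age predictor against the saturated
age-group model backs the linearity assumption per endpoint, and
`decline_report()` assembles the cross-endpoint comparison with pairwise
CI-separation statements. See `vignette("decline-rates")` for the full
methodology.

## Worked example

```r
library(spinedecline)

## the 15 bundled endpoint tables (8 prevalence + 7 continuous)
fx <- spine_fixtures()

## deterministic logistic-AME path
d <- decline_rate(fx[["disk degeneration"]])
d
#> Yearly decline rate, disk degeneration (Brinjikji, logistic-AME):
#>   1.429 %/year (se 0.106, 95% CI 1.221 to 1.637), n = 1603
```

Disk degeneration prevalence rises by 1.43 percentage points per year of
adult age; the reconstruction uses 1603 synthetic subjects, matching the
source sample.

```r
## Monte Carlo path for a muscle endpoint
p <- decline_rate(fx[["Psoas (V)"]], iterations = 10000,
                  rng = rng_spec(1, "Psoas (V)"))
p
#> Yearly decline rate, Psoas (V) (Valentin, MC-gaussian):
#>   0.045 %/year (se 0.023, 95% CI 0.000 to 0.090), n = 24

## the full comparison (fastest decline first)
rep <- run_pipeline(iterations = 10000, seed = 1)
head(as.data.frame(rep), 3)
#>            endpoint    source estimate    ci_low  ci_high       method
#> 1  disk signal loss Brinjikji 1.938794 1.4723736 2.405215 logistic-AME
#> 2 disk degeneration Brinjikji 1.429067 1.2214706 1.636663 logistic-AME
#> 3  disk height loss Brinjikji 1.065081 0.6254932 1.504668 logistic-AME
```

Psoas fat infiltration grows by only ~0.05 FI%/year — the slowest of all
15 endpoints — while disk signal loss declines fastest (1.94 %/year);
`rep$separated` records which endpoints' CIs are cleanly below which.
The report exports as CSV/JSON/plot-data (`export_report()`) and plots as
a point-and-whisker comparison (`plot(rep)`).

A thin command-line wrapper over the same functions is provided:

```sh
Rscript scripts/decline-cli.R fit-prevalence --endpoint "disk degeneration"
Rscript scripts/decline-cli.R mc-continuous --endpoint "Psoas (V)" \
    --iterations 10000 --seed 1
Rscript scripts/decline-cli.R report --format plot-data --out fig.csv
Rscript scripts/decline-cli.R recover --slope 0.2 --seed 7
```

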
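# etdiff

Quantifying localized corneal epithelial thickness (ET) irregularity for
early keratoconus screening.

In keratoconus the epithelium thins over the stromal cone and thickens in a
ring around it, so the ET map becomes locally irregular — typically in the
paracentral inferior-temporal region — well before Scheimpflug tomography
flags the cornea. `etdiff` works on the 41-zone, 7-mm zonal ET maps
reported by anterior-segment OCT devices (one central disc plus five
annuli × eight octants) and computes, for every zone *a* with neighbours
*x*₁ … *x*ₙ, the **inter-zonal ET difference**

```
D(a) = (1/n) Σᵢ |ET(a) − ET(xᵢ)|        (µm)
```

From the difference map two screening parameters are derived:

* the **localized (inferior-temporal) parameter** `(D(cI) + D(cTI)) / 2`,
  the mean difference of the paracentral inferior (cI) and paracentral
  inferior-temporal (cTI) zones, where keratoconic thinning concentrates;
* the **global parameter**, the mean of all 41 zone differences.

The package implements the full two-stage screening analysis around the
statistic — per-zone ROC with data-driven zone selection, AUC with DeLong
confidence intervals, sensitivity-/specificity-driven cut-off derivation,
Mann–Whitney group comparisons with Bonferroni correction, Spearman
correlation with tomographic indices (BAD-D, Belin ABCD), intra-subject
repeatability — plus a synthetic zonal-map cohort generator so the whole
pipeline is testable without patient data. Laterality is handled by
mirroring left eyes onto the right-eye convention so "temporal" means the
same direction cohort-wide.

## Worked example

Simulate a development cohort (86 keratoconus vs 40 healthy eyes, one
measurement each), derive the parameter and its cut-offs, then validate on
an independent cohort of 21 tomographically significant keratoconus eyes,
21 tomographically normal fellow eyes and 21 healthy controls (three
measurements each):

```r
library(etdiff)

dev_cohort <- simulate_development_cohort(seed = 42)
fit <- run_development(dev_cohort)
summary(fit)
#> Parameter development (86 keratoconus vs 40 healthy eyes)
#> Top-2 zones by per-zone AUC: cI (0.998), cTI (0.997)
#>   localized parameter (zones cI+cTI): AUC 0.999 (0.997-1.000)
#>   global parameter: AUC 0.983 (0.965-1.000)
#>   localized cut-offs: lower 1.65 um (sens 95.3%, spec 100.0%), ...
#>   best zonal-ET AUC (comparator): 0.963

val <- run_validation(simulate_validation_cohort(seed = 43), cutoffs = fit)
print(val)
#> Parameter validation
#>   group medians (IQR), um:
#>  parameter            group  n median    iqr
#>  localized          healthy 21  0.646 0.1911
#>  localized KC_fellow_normal 21  1.009 0.4963
#>  localized   KC_significant 21  4.305 2.5951
#>  ...
#>   localized: KC_significant vs healthy p=3.125e-08*;
#>              KC_fellow_normal vs healthy p=1.99e-06*  (alpha 0.0125)
#>   repeatability: median zonal-ET intra-subject SD 0.49 um
```

Reading the output: the per-zone ROC singles out cI and cTI as the most
discriminative zones; the localized parameter separates keratoconus from
healthy eyes better than any single zonal ET value; in validation the
group medians order healthy < fellow < significant, i.e. the statistic is
already elevated in eyes whose tomography still looks normal — the
screening signal of interest. The four Mann–Whitney comparisons are tested
at the Bonferroni-adjusted level 0.05/4 = 0.0125.

Per-eye scoring and map rendering:

```r
d <- interzonal_differences(synth_keratoconus_map(severity = 8, seed = 1))
inferior_temporal_parameter(d)   # µm
plot_zone_map(d, highlight = c("cI", "cTI"))
```

A command-line front end with `simulate` / `develop` / `validate` /
`score` / `render` verbs is installed at `inst/cli/etdiff.R`.

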
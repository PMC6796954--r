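# traitfilter

Trait-based detection of environmental filtering in pollinator
communities along elevation gradients.

Montane pollinator communities shift from bee- to fly-dominated as
elevation rises. If cold high-elevation sites *filter* community
membership by thermal traits, two signatures should appear: the
community-weighted mean (CWM) of body volume and body darkness should
rise with elevation, and the *range* of trait values inside a community
sample should contract relative to random assembly from the regional
pool. `traitfilter` implements the complete analysis for pan-trap
("pollinator cup") surveys, plus a synthetic-data generator that emulates
the full study design, so every stage is testable without field data.

The core statistic is the standardized effect size of the within-sample
trait range. For a cup sample of *k* individuals, a null distribution of
ranges is built by drawing *k* individuals without replacement from the
regional pool (all individuals of the taxon across the gradient) *B* =
1,000 times (exhaustive enumeration replaces sampling when the subset
count is small):

    sesRange_paper = (obsRange − nullRange) / nullRange     # null-mean normalized
    sesRange_sd    = (obsRange − nullMean)  / nullSD        # SD normalized (default)

Samples with `|SES| ≥ 1.96` (SD mode, two-tailed) are classified as
`strong_filter` (negative: range narrower than null) or `weak_filter`
(positive); zone-level patterns are summarised with one-way ANOVA + Tukey
HSD on cup-level CWM and SES, and within-species trends across zones are
tested per species. Specimen traits can also be measured from three-view
images: ellipsoid volume `V = π/6·L·W·H` (head excluded by mask) and
median body darkness on a 0 (white) – 222 (black) scale.

## Worked example

```r
library(traitfilter)

run <- run_pipeline(generator_config(), seed = 1, B = 1000)
run
#> traitfilter run (seed 1, B = 1000, mode = sd)
#>   1922 specimens in 174 cup samples
#>   zone ANOVAs:
#>    metric taxon    trait       F df1 df2         p
#>       cwm   bee   volume 175.812   2  94 1.720e-32
#>       cwm   bee darkness 657.891   2  94 5.332e-56
#>       cwm   fly   volume  77.428   2  74 7.207e-19
#>       cwm   fly darkness  29.110   2  74 4.715e-10
#>  sesRange   bee   volume   3.734   2  79 2.822e-02
#>  sesRange   bee darkness  11.607   2  79 3.807e-05
#>  sesRange   fly   volume  28.766   2  53 3.474e-09
#>  sesRange   fly darkness   1.243   2  53 2.968e-01

st <- run$ses_table
round(with(st[st$trait == "darkness", ],
           tapply(ses_sd, list(life_zone, taxon), mean)), 2)
#>                 bee   fly
#> mixed_conifer -1.84 -0.21
#> ponderosa     -1.44 -0.11
#> spruce_fir    -3.33 -0.59
```

Reading the output: CWM of every trait rises strongly with life zone for
both taxa (the `cwm` ANOVAs), but only *bee* trait ranges contract
beyond the ±1.96 null band, and only at the top (spruce-fir) zone —
mean `ses_sd` of bee darkness is −3.33 there (a strong environmental
filter) versus −1.4 to −1.8 lower down, while fly zone means stay within
±0.6 everywhere (no filtering). That asymmetry — bees filtered at high
elevation, flies not — is the headline pattern the pipeline is designed
to detect.

Individual stages are available as plain functions
(`assemble_dataset()`, `group_samples()`, `cwm()`, `trait_range()`,
`ses_table()`, `zone_summary()`, `intraspecific_trends()`,
`render_specimen()` / `measure_specimen()`), and
`inst/cli/traitfilter.R` provides a `generate|measure|cwm|ses|anova|run`
command-line front end. See the vignette
(`vignettes/trait-filtering-methods.Rmd`) for the model, the generator's
assumptions and the package's limitations.

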
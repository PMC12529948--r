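# estroEDA

Effect-directed analysis (EDA) asks a deceptively simple question about a
complex environmental sample: *which* compound in the chemical soup is
actually causing the biological effect? `estroEDA` implements the
computational arm of an EDA workflow for estrogenic leachates of rubber and
elastomer materials, where the driver of the effect is the redox couple of
4-hydroxydiphenylamine (4HDPA, the phenolic, estrogen-receptor-active
species) and *N*-phenyl-*p*-benzoquinone monoimine (QMI, its oxidized
partner).

The package is aimed at environmental analytical chemists and ecotoxicologists
who combine nontarget LC-HRMS screening with the yeast estrogen screen (YES)
and want the whole evidence chain — feature prioritization, potency
estimation, quantification, speciation and effect balance — reproducible in
code.

## What it computes

1. **Feature prioritization.** Starting from LC-HRMS feature tables (m/z,
   retention time, intensity) of a 5× and 1× enriched extract, two
   thin-layer-chromatography fractions and a process blank, a six-step
   cascade reduces thousands of features to a handful of candidate drivers:
   presence in both enrichment levels, presence in the fractions,
   enrichment monotonicity (intensity must not decrease from 1× to 5×),
   blank subtraction, presence in *both* fractions, and a >1 % relative
   intensity filter. Matching uses 10 mDa MS1 and 1 min RT tolerances.
2. **Exact-mass utilities.** Monoisotopic masses from CODATA atomic masses
   and [M+H]⁺ / [M−H]⁻ adduct m/z with the electron-corrected proton mass
   (1.0072765 Da), plus trace-level peak picking (minimum intensity 10
   counts, S/N ≥ 3 against a MAD-based noise estimate, FWHM 5–60 s) and
   spectral-library matching with Schymanski-style confidence levels 1–4.
3. **Dose–response modelling.** Four-parameter logistic fits
   r(c) = θ_min + (θ_max − θ_min) / (1 + (EC50/c)^h), effect concentrations
   EC_p = EC50 · (p/(100−p))^{1/h} with delta-method 95 % CIs, and
   17β-estradiol equivalents (E2-EQ) of a sample dilution series read
   against the positive-control curve.
4. **Standard-addition quantification** (DIN 32633 style): response vs
   spike regression, x-intercept concentration with a Fieller-type CI,
   dilution correction, and LOD/LOQ by S/N 3 and 10 extrapolation.
5. **Redox speciation kinetics.** IS-normalized species fractions,
   a <4 % mass-balance diagnostic, linear and exponential-plateau fits of
   the reduced-species fraction over time per pH, and Henderson–Hasselbalch
   speciation.
6. **Effect balance.** REP = EC10(E2)/EC10(analyte),
   E2-EQ(analyte) = REP × C, and the percent of the sample's total
   estrogenicity explained, with first-order Gaussian propagation of all
   95 % confidence half-widths.

A synthetic-data module generates every one of these inputs with known
ground truth, so the full pipeline runs — and is tested — end to end without
any instrument data.

## Worked example

The effect-balance chain on measured inputs — EC10(E2) = 19 ± 3 ng/L,
EC10(4HDPA) = 329,000 ± 59,000 ng/L, a leachate 4HDPA concentration of
3000 ± 170 µg/L and a sample potential of 140 ± 7 ng/L E2-EQ:

```r
library(estroEDA)
eb <- effectBalance(ValueWithCI(19, 3), ValueWithCI(329000, 59000),
                    ValueWithCI(3e6, 1.7e5),   # 3000 ug/L in ng/L
                    ValueWithCI(140, 7))
eb
#> Effect balance
#>   REP          : 5.78e-05 ± 1.4e-05
#>   E2-EQ analyte: 173 ± 43 ng/L
#>   E2-EQ sample : 140 ± 7 ng/L
#>   contribution : 124 ± 31 %
```

At two significant figures the analyte explains 120 ± 30 % of the
observed estrogenicity — an effect balance that closes within its
uncertainty, identifying the redox couple as the main driver.

The full synthetic pipeline, seeded for reproducibility:

```r
res <- runPipeline(defaultConfig(seed = 1))
res$cascade
#> Prioritization cascade (positive)
#>   1. detected in 5x and 1x extract                 82
#>   2. present in upper or lower fraction            82
#>   3. 1x intensity <= 5x intensity                  62
#>   4. not in process blank                          42
#>   5. present in both fractions                     2
#>   6. intensity > 1% of 5x total                    2
res$quant
#> Standard-addition quantification
#>   in-assay: 526.7 ± 93 ug/L
#>   sample (x6 dilution): 3160 ± 558 ug/L
res$kinetics$`5`
#> Kinetic fit (linear)
#>    f0 = 0.918946, slope = -0.000644056
#>   R^2 = 0.9557
```

The two surviving cascade features are exactly the planted drivers; the
standard addition recovers the true 3000 µg/L within its CI; and the pH 5
speciation series declines linearly with slope ≈ −6.6 × 10⁻⁴ h⁻¹.

A thin command-line wrapper with subcommands (`simulate`, `prioritize`,
`fit-dose-response`, `quantify`, `balance`, `kinetics`, `run-all`) lives in
`inst/scripts/eda-cli.R`.

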
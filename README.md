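# earscreen

Screening-level assessment of **estrogenic chemical mixtures** in
environmental monitoring data, for ecotoxicologists and monitoring programs
who have multi-matrix chemistry tables (marine water, treatment-plant
effluent, mussel/fish tissue, fish bile) and want to know *which sites,
samples and chemicals deserve attention* for estrogen-receptor-mediated
effects.

## The method

Classical estradiol equivalency factors (EEFs) cover only a handful of
chemicals. `earscreen` instead leans on high-throughput in vitro (HTS)
bioactivity: for each chemical, the activity concentrations at cutoff (ACC)
across its active estrogen-receptor agonist assays are aggregated into a
conservative potency,

    ACC5 [µg/L] = 10^( 5th percentile of log10 ACC [µM] ) × MW,

and each measured concentration becomes an exposure-activity ratio
EAR = C / ACC5 (tissue concentrations back-calculated to water through
bioconcentration factors; bile ng/mL used directly). Per sample, EARs sum
under concentration addition into an `EAR_mix`. Assay-active chemicals with
an estrogen-receptor pathway-model AUC ≤ 0.01 are excluded as likely false
positives.

Effect anchoring: the 17β-estradiol vitellogenin-induction benchmarks in
male zebrafish (NOEC 0.005 µg/L, LOEC 0.025 µg/L) are translated onto the
EAR scale through the median per-sample EAR_mix/EEQ_mix ratio (default 27),
giving water thresholds NOEC_EAR = 0.135 and LOEC_EAR = 0.675 (reported
0.14 / 0.68), and — via the 4000–13000 range of bile-water accumulation
factors for estradiol — bile thresholds NOEC_bEAR 540–1755 and LOEC_bEAR
2700–8775 (reported 540–1800 / 2700–8800). Sites are classified by the
95th percentile of EAR_mix against the bile threshold ranges; samples are
classed low/medium/high; chemicals in medium/high samples are walked
through a decision tree into **driver** (individually exceeds the governing
threshold), **major contributor** (≥ 1 % of the mixture) or **minor
contributor**, then resolved across samples into high-priority / watch-list
/ low-priority / insufficient-information categories.

A synthetic campaign generator with a ground-truth ledger
(`generate_campaign()`) makes the whole pipeline testable without any
external data.

## Worked example

```r
library(earscreen)
camp <- generate_campaign(campaign_config(
  n_sites = 6, samples_per_site = 15, matrix_mix = c(bile = 1),
  female_frac = 0,
  driver_spec = list(list(cas = "SYN-001", median_ear = 900)),
  seed = 7))
res <- ear_screen(camp$chemicals, camp$assays, camp$samples)
summary(res)
```

```
Estrogenic mixture screen (exposure-activity ratios)
  chemicals: 30 (6 active e-EDCs, 16 inactive, 4 excluded low-AUC, 4 insufficient info)
  samples:   90 (20 high, 53 medium, 17 low estrogenic activity)
  sites:     6 (0 low / 1 medium / 4 high-low-certainty / 1 high-high-certainty)
  calibration ratio: 27 (configured)
  priorities: 1 high priority, 0 watch list, 5 low priority, 4 insufficient information

EAR effect thresholds (unrounded; 2-sig-fig report in parentheses)
  water: NOEC_EAR 0.135 (0.14)  LOEC_EAR 0.675 (0.68)
  bile:  NOEC_bEAR 540-1755 (540-1.8e+03)
         LOEC_bEAR 2700-8775 (2.7e+03-8.8e+03)
  benchmarks: NOEC 0.005, LOEC 0.025 ug/L; ratio 27; BCF_bw 4000-13000

Site classification:
 site_id n_samples p95_ear_mix          site_class
 site_01        15    3181.656  high_low_certainty
 site_02        15    6299.948  high_low_certainty
 site_03        15    4193.815  high_low_certainty
 site_04        15    2415.023              medium
 site_05        15   18045.531 high_high_certainty
 site_06        15    4248.077  high_low_certainty

Chemical priorities:
     cas                 category        roles_seen n_supporting_samples
 SYN-001            high_priority            driver                   73
 SYN-002             low_priority minor_contributor                   71
 ...

Single-chemical exceedance: 100% of 73 samples above NOEC; 100% of 20 above LOEC
```

Reading it: the one chemical forced to a median EAR of 900 (a dominant
steroid scenario) drives 20 of 90 bile samples past the high-activity
threshold and lands in the high-priority category; the five weaker true
e-EDCs never reach 1 % of any exceeding mixture and stay low priority; the
four chemicals absent from the assay roster are flagged insufficient
information rather than silently dropped. One site stays in the medium
region and one clears the highest LOEC_bEAR with high certainty.

The bundled published site summary reproduces the reference site
classification exercise:

```r
s <- salish_site_summary()
table(classify_site(s$p95_ear_mix, derive_thresholds()))
#>   low    medium    high_low_certainty    high_high_certainty
#>     2        11                     3                      2
```

A thin command-line wrapper with `run`, `simulate`, `classify-sites` and
`thresholds` subcommands lives at `inst/scripts/earscreen-cli.R`.

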
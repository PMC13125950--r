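# scatCMR

Non-invasive genetic capture-mark-recapture from scat genotypes.

Monitoring trap-averse or stress-sensitive mammals (small macropods in
fenced conservation reserves are the motivating case) is often only
feasible by collecting faecal pellets along transects, genotyping the
scat DNA, working out which pellets came from the same animal, and
estimating abundance by spatially explicit capture-recapture (SECR).
Scat DNA is degraded: calls go missing, heterozygotes drop an allele
(ADO), and artefact alleles appear (FA). `scatCMR` implements the
whole workflow with those failure modes as first-class citizens:

* **Panel power & filtering** — a locus filtering cascade (depth, call
  rate, MAF, HWE, heterozygosity window, LD pruning) with a per-step
  audit, and probability-of-identity power curves. For a locus with
  allele frequencies *p<sub>i</sub>*:

  PID = Σ p<sub>i</sub>⁴ + Σ<sub>i&lt;j</sub> (2 p<sub>i</sub> p<sub>j</sub>)²
  and
  PID<sub>sib</sub> = 0.25 + 0.5 Σ p<sub>i</sub>² + 0.5 (Σ p<sub>i</sub>²)² − 0.25 Σ p<sub>i</sub>⁴,

  multiplied cumulatively over loci to find the smallest panel
  reaching an identification threshold.
* **Replicate-genotype QC** — amplification rates, consensus calling
  with a fill-in floor, ADO/FA estimation from replicate pairs, and
  staged sample/locus filtering.
* **Individual identification** — pairwise allelic mismatch counts,
  hierarchical clustering cut at a mismatch threshold *h*, elbow and
  percentile diagnostics for choosing *h*, capture-history
  construction, and cross-method assignment concordance.
* **Population genetics** — per-session diversity (Na, Ho, He, F),
  Mann-Whitney between-session tests, Ritland pairwise relatedness,
  and LD-method effective population size (Burrows disequilibrium with
  the Waples 2006 bias corrections and parametric chi-square CI).
* **SECR** — the full Poisson count-detector likelihood over a habitat
  mask (half-normal, hazard-rate or negative-exponential detection),
  habitat/session density models on a log link, AICc ranking with a
  5-unit similarity window, and abundance as the density × area sum
  product with delta-method SEs.
* **Synthetic surveys** — a generator reproducing a 99-detector,
  two-session transect design with habitat mosaics, Poisson
  detections and realistic genotyping noise, with ground truth
  attached, so every stage is testable against known answers.

## Worked example

```r
library(scatCMR)

# How many ideal SNPs does individual identification need?
pid_curve(snp_loci(46, maf = 0.5))
#> pid_curve over 46 loci, threshold 0.0001
#>   loci needed: 10 (unrelated), 18 (siblings)

# A full synthetic survey, then the complete pipeline
st <- simulate_study(seed = 42)          # 112 scat samples, 2 sessions
res <- run_pipeline(st$gt, st$layout, habitat = st$habitat)
#> [scatCMR] QC: 224 runs, 46 loci
#> [scatCMR] QC: dropped 8 runs / 0 loci at the 0.2 stage; floors removed 10 runs and 23 loci
#> [scatCMR] consensus: 111 samples x 23 loci
#> [scatCMR] clustering: 50 individuals at h = 3
#> [scatCMR] capture history: 111 detections = 50 individuals + 61 recaptures
#> [scatCMR] suggested buffer: 330 m

res$qc$errors
#> error_rates over 112 replicate pairs:
#>   allelic dropout 0.040 (+/- 0.004 SE)
#>   false alleles   0.001 (+/- 0.000 SE)

res$abundance[res$abundance$habitat == "TOTAL", ]
#>  session habitat    density area_ha        N       se
#>     2020   TOTAL 0.09672145     980 94.78703 17.45588
#>     2021   TOTAL 0.09672145     980 94.78703 17.45588
```

Reading the output: the recovered dropout rate (0.040) matches the
SNP-preset noise injected by the generator (0.045); 111 surviving
samples cluster into 50 individuals at *h* = 3 (the generator placed
121 animals on the wider simulated region, of which those near the
transects are detectable); and the fitted density, 0.097 animals/ha,
integrates to an expected 94.8 ± 17.5 animals on the 980-ha buffered
mask — density is the estimand, and abundance refers to the masked
region around the detector array. Per-habitat density models,
alternative detection functions and AICc comparison are available via
`fit_secr()` / `aicc_table()` directly.

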
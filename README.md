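# fragscreen

PCR-based analysis of cell-free DNA (cfDNA) fragmentation and sample
quality.

Plasma cfDNA is released mostly as nucleosome-protected fragments of
~170 bp, and its length profile carries two very different kinds of
signal. Biologically, chromatin state in the cells of origin shapes
fragment sizes: nucleosome-depleted open chromatin yields shorter, more
variable fragments than densely packed loci, and cancer patients show an
excess of sub-mononucleosomal fragments. Technically, high-molecular-weight
(HMW) genomic DNA leaking from blood cells lysed during collection or
storage contaminates the sample and masks those native features. Both
signals can be read out without sequencing, using the dependence of PCR
amplification on fragment length: a fragment can only template an amplicon
it fully contains, so short amplicons count (nearly) all copies while long
amplicons count only long fragments.

`fragscreen` implements that programme end to end for laboratories using
droplet digital PCR (ddPCR), real-time qPCR and automated electrophoresis
(AEF), together with a synthetic-data generator that emulates cfDNA
fragment-length structure so the whole pipeline is testable without any
external data.

## What it computes

* **Amplicon containment model.** The probability that a fragment of
  length *L* fully contains an *A*-bp amplicon under uniform random
  breakpoints is `max(0, L − A + 1) / L`; expected amplifiable copies in a
  reaction are `(m / 3.3 pg) · c · Σ L f(L) p(L, A) / Σ L f(L)` for input
  mass *m*, assay copy number *c* and empirical length distribution
  *f* (so 1 ng of intact human DNA ≈ 303 haploid copies). A brute-force
  fragmentation simulator ships as the independent oracle for the closed
  form.
* **ddPCR Poisson quantification.** From a well with a fraction *p* of
  positive droplets, `λ = −ln(1 − p)` copies per droplet, converted to
  copies/µL and copies/ng with Wilson-interval confidence bounds; plus the
  per-region fragmentation statistics: the short−long copy difference and
  the short/long ratio.
* **HMW contamination score.** ΔΔCq relative quantification of a 612 bp vs
  a 106 bp multicopy amplicon (106 bp as reference), calibrated against a
  50%-HMW standard: `percent = E^(−ΔΔCq) × 50`. Batch screening flags
  samples above a threshold; a standards panel (1/5/25/50% HMW) validates
  recovery.
* **AEF cross-validation.** Conversion of size–concentration traces to
  molar density (`mass / (L · 650 g/mol/bp)`), the ratio of molarities
  above the two amplicon cutoffs, and detection of di-/tri-nucleosome
  degradation peaks (360–400, 540–600 bp) that appear in stored blood.
* **Region summaries and cohort statistics.** Midpoint assignment of
  fragment intervals to target regions with median/IQR summaries, Levene's
  variance-homogeneity test, Wilcoxon rank-sum comparisons, and Pearson
  correlation with Fisher-z intervals on both *r* and *R²*.

## Worked example

Simulate a healthy-donor cfDNA sample, quantify it with a short/long ddPCR
assay pair in an open-chromatin region, and summarize fragmentation:

```r
library(fragscreen)

pop <- simulate_fragments(healthy_cfdna_spec(), 10000, seed = 7,
                          sample_id = "H01")
median(pop$length_bp)
#> [1] 170

assays <- default_region_assays()
plate <- dplyr::bind_rows(
  simulate_droplets(pop, assays$OCR1_short, input_mass_ng = 1, seed = 7),
  simulate_droplets(pop, assays$OCR1_long,  input_mass_ng = 1, seed = 8)
)
est <- poisson_quantify(plate)
est[, c("assay_name", "copies_per_ng", "ci_low", "ci_high")]
#>   assay_name copies_per_ng ci_low ci_high
#> 1 OCR1_short         212.7  183.8  246.14
#> 2  OCR1_long          25.9   17.1   39.21

fragmentation_summary(est)[, c("difference", "ratio")]
#>   difference ratio
#> 1      186.8 8.214
```

The short amplicon reports ~213 of the ~303 theoretical copies per ng
(fragments shorter than 70 bp escape it), the long amplicon only ~26
(few 170 bp fragments span 160 bp), so this sample shows a short−long
difference of ~187 copies/ng and an integrity ratio of ~8 — the two
statistics compared between cohorts and regions.

Contamination screening is calibrated by the standards panel and
cross-validated against electrophoresis:

```r
res <- run_experiment("contamination_panel", seed = 1)
res$panel_recovery
#>   sample_id true_percent idealized_percent containment_percent
#> 1  std_1pct            1                 1                1.41
#> 2  std_5pct            5                 5                8.78
#> 3 std_25pct           25                25               30.87
#> 4 std_50pct           50                50               50.00
res$matched_correlation[, c("r", "r_squared")]
#>        r r_squared
#> 1 -0.952     0.906
```

Under idealized detectability the ΔΔCq score recovers the panel exactly;
under the length-containment model low fractions are biased upward (a
documented model property), and across a 16-sample matched batch the qPCR
score and the AEF molarity ratio agree (R² ≈ 0.9 on the log scale).

Other one-command experiments: `run_experiment("fragmentation_cohort")`
(32 healthy vs 53 CRC subjects, three regions, Wilcoxon and Levene
reports), `"storage_series"` (blood stored 2–10 days, degradation peaks
after day 7), `"batch_screen"` (16-sample screen flagging two spiked
samples). Each writes a CSV report bundle via `out_dir =`.

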
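---
title: "Models and methods behind fragscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fragscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragscreen)
```

`fragscreen` analyses cell-free DNA (cfDNA) fragmentation with PCR-derived
data: droplet digital PCR (ddPCR) copy statistics over open and closed
chromatin loci, a ΔΔCq qPCR screen for high-molecular-weight (HMW)
genomic-DNA contamination, and automated-electrophoresis (AEF)
cross-validation. This vignette explains the models, their assumptions,
the tunable parameters, and the design decisions, in the package's own
terms.

## The containment model: from fragment length to PCR signal

A PCR amplicon of length $A$ can only be produced from a template fragment
that fully contains it. Treating fragmentation breakpoints as uniform at
random, a fragment of length $L$ that covers the amplicon's first base
contains the whole amplicon with probability

$$p(L, A) = \frac{\max(0,\, L - A + 1)}{L},$$

which is 0 for $L < A$, $1/A$ at $L = A$, and tends to 1 as $L/A \to
\infty$. This is the package's central mechanistic assumption; a
brute-force simulator (`simulate_containment_probability()`) that places
fragments at random over a fixed window is kept in the package as an
independent oracle and is checked against the closed form in the tests.

Expected amplifiable copies in a reaction combine three factors:

$$\mathbb{E}[\text{copies}] \;=\; \frac{m}{3.3\ \text{pg}} \cdot c \cdot
\frac{\sum_L L\, f(L)\, p(L, A)}{\sum_L L\, f(L)},$$

with $m$ the input DNA mass, $3.3$ pg the mass of one haploid human genome
(so 1 ng $\approx$ 303 haploid copies), $c$ the assay's genomic copy
number, and $f$ the sample's empirical fragment-length distribution. The
containment average is *length-biased*: a genomic target locus lies on a
fragment with probability proportional to that fragment's length, so a
15 kb molecule carries ~90-fold more target loci than a 170 bp fragment.
The count-weighted alternative, $\sum_L f(L) p(L,A)$, looks similar but
under-weights long molecules; it would make the contamination assay's
low-fraction recovery biased *downward*, the opposite of both the physics
and the observed behaviour of the length-biased form. For single-length
populations the two coincide (1 ng of uniform 170 bp DNA with a
single-copy 106 bp assay gives $303 \times 65/170 \approx 115.9$ copies).

Monotonicity follows directly: for a fixed sample, expected copies are
non-increasing in amplicon length, which is why a short/long amplicon pair
reads out fragmentation — heavily fragmented DNA shows a steep decline
from short to long, intact DNA a shallow one.

## ddPCR quantification

Each well partitions the reaction into droplets of volume $v$ (default
0.85 nL, the common droplet-generator convention; overridable per well).
With a fraction $p$ of positive droplets, Poisson occupancy gives
$\lambda = -\ln(1-p)$ mean copies per droplet, hence
$\lambda / v$ copies/µL and
$\text{copies/ng} = (\lambda/v) \cdot V / m$ for reaction volume $V$
(default 20 µL) and input mass $m$.

Confidence intervals are Wilson score intervals on $p$ pushed through the
monotone transform $-\ln(1-p)$. The Wilson interval was chosen for its
behaviour at the boundaries: at $p = 0$ the lower bound is exactly 0, and
near saturation it stays inside $[0, 1]$. Saturated wells ($p = 1$) leave
$\lambda$ undefined; they are reported as `Inf` with `saturated_flag` set
rather than any finite stand-in. Wells under 8,000 accepted droplets are
flagged low-quality (a vendor rule of thumb) but not dropped.

Two fragmentation statistics are derived per sample and region from the
short/long assay pair: the **difference** (short − long copies/ng) and
the **ratio** (short / long, undefined and flagged when the long estimate
is 0). Both are consistent across droplet counts; only their sampling
variance shrinks with more droplets.

## The ΔΔCq contamination score

The screen exploits a multicopy target (~25 primer annealing sites per
haploid genome, so 1 ng of input suffices) amplified as a 106 bp and a
612 bp product. Native mononucleosomal cfDNA (~170 bp) templates only the
106 bp amplicon; HMW contamination templates both. With the 106 bp
amplicon as reference and the 50%-HMW standard as calibrator:

$$\Delta Cq = \overline{Cq}_{612} - \overline{Cq}_{106}, \qquad
\Delta\Delta Cq = \Delta Cq_{\text{sample}} - \Delta Cq_{\text{control}},$$
$$\text{RNE} = E^{-\Delta\Delta Cq}, \qquad
\text{percent HMW} = \text{RNE} \times 50\%.$$

Scoring the control against itself gives exactly 50% by construction —
the package's basic self-consistency check. Under the idealized
detectability assumption (short amplifies from all mass, long only from
HMW mass) the noiseless score recovers the panel fractions 1/5/25/50%
exactly; this algebraic identity is what makes the mixed-mass standards a
calibration ladder.

Decisions where practice varies:

* **Efficiency.** Default is $E = 2.0$ (perfect doubling) for both assays,
  because standard-curve efficiencies are rarely available at screening
  time; `efficiency_mode = "per_assay"` applies per-assay efficiencies
  Pfaffl-style, $\text{RNE} = E_{612}^{\Delta Cq_{612}} /
  E_{106}^{\Delta Cq_{106}}$ (control minus sample in each exponent).
* **Replicates** are aggregated by the arithmetic mean of detected Cq.
* **Non-detects.** The thermocycling program runs 40 cycles, so any Cq
  $\ge 40$ (or missing) is a non-detect. A sample whose long amplicon
  never detects is below the quantification limit: the score is `NA` with
  `below_loq` set and an upper bound computed at Cq = 40 — never a silent
  zero.
* The assay pair is modelled monoplex; no cross-talk terms exist in the
  data model.

With realistic length-containment detectability instead of the idealized
assumption, recovered percentages at low fractions are biased upward
(e.g. the 1% standard reads ~1.2–1.8%): the short amplicon also gains
signal from the HMW molecules, shrinking its Cq and inflating RNE. This
bias is a property of the assay model, documented and pinned by a
regression test rather than hidden.

## Electrophoresis cross-validation

AEF reports mass concentration against size. Since one mole of $L$-bp DNA
weighs $L \times 650$ g (650 g/mol/bp), molar density is
$\text{mass}(L) / (L \cdot 650)$. The cross-validation statistic is the
ratio of molarity above 106 bp to molarity above 612 bp, computed as
trapezoidal above-cut integrals on the trace grid (synthetic traces use a
1 bp grid). The above-cut-integral definition was chosen over vendor
"smear region" tables as it is explicit and instrument-independent. The
ratio is invariant to rescaling the trace, decreases as HMW mass is
added, and degenerates to the `Inf` sentinel (not an error) for samples
with no molarity above 612 bp. Degradation peaks are located by local
maxima of a Savitzky–Golay-smoothed trace (quadratic, 15-point window)
inside the di- and tri-nucleosome windows 360–400 and 540–600 bp.

## Fragment intervals and regions

Fragments (BED, 0-based half-open) are assigned to target regions by
**midpoint containment**: `region_start <= floor((start+end)/2) <
region_end`. Midpoint assignment makes the result a partition on disjoint
regions — a fragment straddling a boundary is never double-counted, which
any-overlap assignment would not guarantee. Strand is ignored: cfDNA
fragments are double-stranded. Per-region summaries are medians and
quartiles with linear interpolation (`quantile()` type 7), so
`{1,2,3,4}` has median 2.5. The shipped
`inst/extdata/regions_synthetic.bed` is a synthetic placeholder for the
open/closed chromatin loci (the real coordinates are not published in a
machine-readable form); analyses of real data should supply their own
region BED.

## Cohort statistics

* `levene_test()` is the classic Levene statistic — one-way ANOVA on
  absolute deviations from the group **mean** (default), with
  `center = "median"` for the Brown–Forsythe variant. The mean-centred
  form is the default because that is the test named in standard usage;
  the test suite cross-checks both centres against an independent
  implementation.
* `rank_sum_test()` is the two-sided Wilcoxon/Mann–Whitney test, exact by
  enumeration for arms of at most 8 without ties (so `{1,2,3}` vs
  `{4,5,6}` gives exactly $p = 2/\binom{6}{3} = 0.1$), and a tie-corrected
  normal approximation with continuity correction otherwise.
* `pearson_with_ci()` returns $r$ with a Fisher-z interval and derives the
  $R^2$ interval by squaring the $r$ endpoints; when the $r$ interval
  spans 0 the $R^2$ lower bound is floored at 0 (the square of an interval
  containing 0 starts at 0).
* No multiple-testing correction is applied by default; the handful of
  planned comparisons are reported raw, and users can `p.adjust()`
  downstream.

## The synthetic-data generator

The generator produces fragment populations as weighted mixtures of
truncated-gaussian and lognormal components, and from them droplet counts,
Cq values and electropherograms through the forward models above. Its
defaults encode the study conditions the package is designed around:

| preset | components | rationale |
|---|---|---|
| healthy cfDNA | gaussian(170, 20) | mononucleosomal peak; healthy median 170 bp, scale keeps the IQR plausible |
| CRC cfDNA | 0.3·gaussian(145, 20) + 0.7·gaussian(170, 20) | excess of sub-mononucleosomal fragments in cancer; weight configurable |
| storage-degraded | 0.5/0.3/0.2 at 170/380/570 bp | mono/di/tri-nucleosome ladder of blood stored past the protective window |
| sheared standard | gaussian(170, 35) | ultrasonically sheared genomic DNA, mean ~170 bp |
| HMW DNA | lognormal(median 15 kb, sdlog 0.5) | intact genomic DNA; true length distribution in stored blood is unknown — the only requirement is being far above 612 bp, and the lognormal default is labelled an assumption |

Mass-based mixing (`mix_by_mass()`) resamples fragment *lengths* from each
source and sets fragment *counts* so the expected base-pair share of the
HMW source equals the nominal mass fraction (stochastic rounding keeps the
expectation exact at small counts). The calibration panel is built at
1/5/25/50% HMW mass. Droplet simulation computes expected copies, converts
to a per-droplet Poisson load via the droplet and reaction volumes, and
scatters copies uniformly over droplets; Cq simulation uses
$Cq = 37 - \log_E(\text{copies})$ plus gaussian replicate noise, with zero
copies a non-detect. Every stochastic function takes an explicit seed and
restores the caller's RNG state; there is no global random state.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: GC-content amplification bias (short
tandem models cannot quantify GC-rich matrices accurately), droplet rain
and partial amplification, sequence-dependent shearing, end-motif and
strand structure, polymerase inhibition, and between-run instrument drift.
Conclusions about such real-data artefacts need real instrument data.

## Scenario experiments and problem sizes

`run_experiment()` reproduces four experiments end to end and writes CSV
report bundles; outputs are byte-identical for a fixed scenario + seed.
The fragmentation cohort uses 32 healthy and 53 CRC subjects (the study's
arm sizes), 4,000 fragments per sample and 20,000 droplets per well — the
sample-level signal saturates well below these sizes, so they keep a full
cohort under a few seconds without changing any conclusion. Between-
subject heterogeneity is modelled as a lognormal per-locus yield factor
(sdlog 0.25 at open-chromatin loci vs 0.06 at the pericentromeric locus),
scaling both amplicons of a region together: this widens the short−long
difference across subjects at open loci (Levene structure) while leaving
the short/long ratio untouched (so the CRC ratio shift remains testable).
The storage series uses two donors at 2/4/7/10 days with HMW fractions
2/5/12/35% and the degraded ladder from day 7; the screening batch has 16
samples with two spiked at 40% HMW and the rest at 2%; the matched
cross-validation batch is 4 replicates of each panel fraction with 0.2
cycles of replicate Cq noise. Test-suite simulation sizes (e.g. 200
droplet replicates for CI coverage, 500/1,000/2,000 repetitions for the
power, coverage and type-I checks) were chosen as the smallest sizes at
which the binomial error of the checked proportion is comfortably inside
the asserted band.

## Known limitations

* The containment model ignores amplicon position within the target
  locus and assumes breakpoints uniform at random; nucleosome-phased
  cleavage violates uniformity in ways the model averages over.
* The designed short/long ddPCR amplicon lengths for the three regions
  are not published; the 70/160 bp defaults are placeholders consistent
  with the "short < 80 bp, long > 150 bp" design rule and should be
  replaced with real assay lengths via `default_region_assays()`.
* The ΔΔCq score saturates for samples far above the 50% calibrator and
  is biased upward at low fractions under realistic detectability; it is
  a screening statistic, not an absolute measurement.
* AEF ratios depend on trace quality below ~100 bp where markers and
  adapter artefacts live; the package assumes marker-corrected traces.
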
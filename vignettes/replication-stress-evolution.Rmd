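---
title: "Models and methods: analysing experimental evolution under replication stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: analysing experimental evolution under replication stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repstress)
library(tibble)
```

`repstress` packages the downstream statistics of a yeast
experimental-evolution workflow: parallel populations carrying a constitutive
replication defect are propagated by daily 1:1000 serial dilution
(~10 generations/cycle) for ~1,000 generations, and adaptation is read out
through sequencing, competition assays and S-phase profiling. This vignette
explains each model, the tunable parameters and their defaults, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the design was genuinely open.

## Convergence testing of recurrently mutated genes

Under neutrality, mutations land uniformly: the count in a gene of effective
length $N$ (coding length plus a regulatory pad, default 1,000 bp per ORF —
500 bp on each side) is $X \sim \mathrm{Poisson}(\lambda N)$, with
$\lambda$ estimated per background as total coding-scope mutations divided by
the summed effective lengths. The recurrence p-value is the upper tail
$P(X \ge n)$. A published variant of this expression,
$1 - \Gamma(n+1, \lambda N)/n!$, equals $P(X \ge n+1)$ — off by one relative
to the "at least $n$" event; `poisson_tail_pvalue()` implements the correct
tail by default and reproduces the off-by-one form under
`legacy_tail = TRUE` for comparability with pipelines that used it.

Multiple testing: Benjamini–Hochberg (α = 0.05) on the focal (perturbed)
background, the more stringent Bonferroni (α = 0.05) on the control
background; control-significant genes are removed from the focal list, since
recurrence there reflects adaptation to the propagation regime (media,
dilution), not to the perturbation. Two open choices are exposed as
arguments: the number of tests $m$ defaults to all genes in the model table
(`m_mode = "all_genes"`), not just mutated ones — the hypotheses exist for
unmutated genes too — and every mutation record counts separately (recurrent
sites are not collapsed).

## Selection coefficients from competition assays

Competing a test strain against a constitutively fluorescent reference, the
expected dynamics are exponential: $\ln r(g) = \ln r_0 + s\,g$ with $r$ the
test:reference event ratio and $g$ cumulative generations,
$g = \log_2(\mathrm{events}_{t24}/\mathrm{events}_{t0})$ per cycle (fallback
$\log_2$ of the dilution factor, ≈ 9.97 for 1:1000). `estimate_selection()`
fits an unweighted free-intercept OLS per biological replicate and reports
the mean and SD of replicate slopes; Welch's unequal-variance t-test
(`compare_fitness()`) compares strains. The day-0 post-mixing measurement is
included at $g = 0$ by default (it is a legitimate, if noisier, point on the
same line; drop it upstream if unwanted). The estimator is exact on
noiseless exponential data for any $s$ and $r_0$, and invariant to uniform
rescaling of the event counts at a timepoint.

Reference frames compose multiplicatively:
`convert_reference_fitness(s, f_ref)` returns $f_\mathrm{ref}(1+s)$ — a
+27% coefficient against a reference at 0.73 of wild type is 0.93, a 7%
residual defect.

## Copy-number profiles

100-bp window depths are divided by the genome-wide median of unmasked
windows (repeat regions — telomeres, rDNA, Ty — enter via a user-supplied
mask BED; there is no built-in repeat finder), the ancestor's normalised
track is subtracted, and the difference is smoothed with a centred five-window
moving mean whose value is reported at the window centre; chromosome ends use
shrunken windows so they retain values. On this scale +1 means one haploid
copy gained during the experiment. Segment calling (runs with
$|\Delta| \ge 0.5$ copies over ≥ 50 windows, split at sign flips) is this
package's addition — chosen to separate ±1-copy steps from Poisson noise at
~50× depth — and is labelled as such; both thresholds are arguments.

## Replication timing

During a synchronous S-phase, a locus' relative coverage runs from 1×
(unreplicated) to 2× (replicated); $t_{rep}$ — the time by which half the
population has replicated it — is where coverage crosses 1.5×, the midpoint.
Each sample's median-normalised track is rescaled so its genome-wide mean
equals the sample's relative DNA content (measured independently from the
cell-cycle profile), Savitzky–Golay smoothed along the genome (window 9 bins,
order 2 by default; the filter family is standard for depth tracks and the
parameters are arguments), and interpolated linearly between the bracketing
timepoints of the first upward crossing. Windows above 1.5× at the first
sample interpolate from an implicit $(t=0, 1.0\times)$ anchor — release from
G1 implies unreplicated at $t=0$; windows never reaching 1.5× are censored
and reported as "later than the last sample", never as a numeric sentinel.
Unreplicated burden at 45 min is the summed length of windows with
$t_{rep} > 45$ or censored.

Origins are local minima (earliest-replicating loci) and terminations local
maxima of the timing profile after a discrete-cosine low-pass filter
(wavelengths ≥ 20 kb kept by default, the scale of yeast replicons).
Descriptions of this step sometimes speak of origins as "peaks" — a plotting
orientation with inverted axes; this package fixes the convention
origins = minima, terminations = maxima of $t_{rep}$. Two numerical choices
matter:

* **Prominence.** Adjacent origin/termination pairs whose filtered timing
  difference is below `min_prominence` (default 5 min) are discarded,
  weakest pair first. With 15-min sampling the interpolated $t_{rep}$ of
  near-deterministic data is quantised to interval midpoints, and low-pass
  filtering of such staircases rings (Gibbs), producing extremum pairs with
  gaps up to ~4 min that are artefacts, not replicons; genuine timing
  contrasts in these designs are at least one sampling interval.
* **Boundaries.** Domain edges (chromosome ends, censored-gap borders) where
  the filtered timing rises outward are reported as boundary terminations —
  forks do terminate there — and flagged so callers can exclude them.

Fork velocity divides origin→termination distance by the timing difference,
one estimate per origin side, keeping only replicons ≥ 30 kb ("long"
replicons; shorter ones have timing differences comparable to their error).
Note that with strictly deterministic firing and 15-min sampling, midpoint
quantisation alone can bias a 25-min replicon's elapsed time by several
minutes — velocity validation is therefore done on simulations with
dispersed firing times (SD ~5 min), which is also the realistic kinetics.

## Fork-stall zones and feature enrichment

Late fork positions (e.g. boundaries of regions unreplicated at 45 min)
become zone centres with ±5 kb flanks, clipped to chromosomes and merged
where overlapping. For each feature class, the observed in-zone count (by
feature midpoint; `by = "any_overlap"` optional) is compared with the
genome-uniform expectation $n \cdot \mathrm{zone\ bp}/\mathrm{genome\ bp}$
by a 1-df χ² over the in/out cells — deliberately uncorrected for GC or
mappability, matching the uniform null it tests. Yates' correction is off by
default (flag available); expected cells below 1 flag the result
`low_count` but the test is still reported.

## Allele trajectories and bulk segregants

Sanger peak heights give per-direction frequencies
$f = h_\mathrm{mut}/(h_\mathrm{mut}+h_\mathrm{anc})$; the two sequencing
directions are averaged first (using all signal) and then clamped — below
the background level (unquantified in chromatogram practice; default 0.05,
configurable) to 0, above 0.95 to 1 — with the same monotone rule applied to
the per-direction bounds so they still bracket the estimate. Trajectories
are assembled without interpolation. Bulk-segregant classification is strict:
pooled frequency > 0.70 after progeny selection is causal; neutral alleles
segregate to ≈ 0.5.

## Cell-cycle metrics

The fraction of the genome replicated is read from the DNA-content
histogram's mode as $(\mathrm{mode} - 1C)/(2C - 1C)\times 100$ — the only
reading of the garbled printed formula that is bounded in $[0, 100]$ and
means "percent replicated"; this interpretation is ours and is stated, not
attributed. Ties break toward lower DNA content; modes outside the span clip
with a warning. The 1C/2C ratio takes the tallest bin within ±10% of the
span around each annotated peak, requiring it to be a local maximum of the
full histogram so a missing peak errors rather than returning a boundary
artefact.

## The synthetic-data module

Every generator emits the statistical structure its analysis stage assumes,
plus the ground truth (`sim_truth()`):

* `simulate_mutations()`: Poisson counts per gene per population; defaults
  (rate 8×10⁻⁵/bp over the experiment, 1,000 genes of N = 2,500 bp, 8
  populations, 10× spike multiplier) give ~1,700 coding mutations per
  background — the scale of an eight-population, 1,000-generation
  experiment — and were fixed by a closed-form power analysis before any
  test was run.
* `simulate_competition()`: binomial sampling of flow events around the
  exponential expectation; `events_per_sample = Inf` is the noiseless limit.
* `simulate_replication_timecourse()`: 10,000 cells by default; firing times
  Normal truncated at 0 (the kinetic law is a modelling stand-in, not a
  mechanistic claim); constant fork speed; stall sites add their delay to
  every fork crossing them; coverage = 1 + replicated fraction, Gaussian
  depth noise (default SD 0.15, ~50× sequencing after binning) added before
  median normalisation.
* `simulate_cnv_tracks()`: Poisson (or negative-binomial, or noiseless)
  counts at 50× around doubled expectations inside duplicated intervals.
* `simulate_feature_annotations()`: placement density multiplied by the
  enrichment factor inside zones, then normalised.

All coordinates are 0-based half-open on fixed 100-bp bins; a fixed seed
gives bit-identical output. What the generators do **not** emulate: read-level
artefacts (mappability, GC bias, PCR duplicates), chromosome-scale
heterogeneity in mutation rate, origin interference/efficiency, clonal
interference within populations, or chromatogram base-calling. Passing tests
therefore demonstrate that the estimators recover the parameters of these
idealised designs — not that real libraries are free of the biases the mask
and normalisation steps exist to absorb.

## Problem sizes and verification

The test suite and `scripts/acceptance.R` run entirely on simulated data at
desk scale: 200 kb–500 kb single-contig genomes, 20–4,000 cells for
replication simulations (deterministic-firing checks need few cells because
all cells are identical), 100–1,000 seed replicates for calibration rates.
These sizes were chosen so the full suite runs in minutes while keeping
Monte-Carlo standard errors well below the tolerances being asserted. The
headline wet-lab numbers of the motivating study (population fitness gains,
chromosome-IV amplification frequencies) derive from deposited sequencing
and are out of desk scope; nothing in the package asserts them.

## Known limitations

* Origin calling reports positions at window resolution after low-pass
  filtering; closely spaced origins (< the cutoff wavelength) merge.
* Fork-velocity estimates assume timing extrema delimit a single replicon;
  hidden passive replication biases them upward near inefficient origins.
* The χ² enrichment test treats features as independent points; clustered
  feature classes (e.g. tandem repeats) violate this and inflate
  significance.
* The competition model assumes constant $s$ across the assay; frequency-
  dependent fitness shows up as curvature the per-replicate regression will
  average over.
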
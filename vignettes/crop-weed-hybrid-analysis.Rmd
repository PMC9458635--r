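---
title: "Dating, mapping and scanning crop-weed hybrid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating, mapping and scanning crop-weed hybrid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedhyb)
```

## The problem

Weedy relatives of self-fertilizing crops occasionally hybridize with the
crop and then return to selfing. In herbicide-resistant rice systems this
produces weeds that carry a crop-derived resistance allele at the
acetolactate synthase locus (*ALS*) on a genome that otherwise drifts — or
is driven — back toward the weedy ancestor. `weedhyb` implements the full
analysis chain for such material: marker discovery between the ancestral
gene pools, dating of the hybridization event, local-ancestry decoding,
genome-wide bias quantification, windowed divergence scans, haplotype
networks at the resistance gene, and phenotype tabulation — together with a
forward simulator that generates cohorts with known truth so that every
estimator can be validated.

## Model and estimators

### Ancestry-informative markers

An AIM is a site fixed for opposite alleles in the two ancestral panels
(`identify_aims()`, default `min_freq_diff = 1`). Both panels must be
called at `min_call_rate = 0.8` of samples at the site; the default guards
fixed-difference calls against missingness and can be relaxed for sparse
panels. The supervised ancestry coefficient of a sample is simply its
A-allele fraction over called AIMs — exact for an F1 (0.5) and unbiased for
later generations, at the price of ignoring linkage (it is a method-of-
moments substitute for a model-based admixture fit, which this package
deliberately does not re-implement).

### Generations since hybridization

Under strict selfing, heterozygosity at AIMs halves each generation,
`E[h_g] = 0.5^g`, so `g_hat = -log2(h)` (`estimate_generations()`). The
confidence interval is Clopper-Pearson on the heterozygote proportion
propagated through `-log2`; the exact interval was chosen because the
relevant samples sit at very small heterozygote counts where normal
approximations misbehave. A sample with zero observed heterozygotes yields
only the open bound `g >= log2(n_AIMs)` and is flagged censored rather
than given a point estimate. The estimator assumes one outcross followed
by strict selfing; repeated outcrossing would make estimates conservative
(too small), and no correction is attempted.

### Local ancestry

`infer_tracks()` decodes crop-allele dosage (0/1/2) along each chromosome
with a three-state HMM over AIM genotypes. Between adjacent AIMs at
distance `d` bp each haplotype switches ancestry with probability
`(1 - exp(-2 * rho * d)) / 2`; genotypes are emitted with per-allele error
`eps`. Defaults `eps = 0.01`, `rho = 1e-7` per bp were set to one expected
ancestry switch per 10 Mb of haplotype — the order implied by a handful of
selfing generations with one or two crossovers per chromosome — and both
are exposed as arguments. The decoded track is the Viterbi path; posteriors
from forward-backward accompany every call. Segment boundaries snap to
midpoints between adjacent AIMs: resolution-honest, deterministic, and
deliberately coarser than the truth (a documented difference from
regularization-path local-ancestry methods, which this HMM replaces).
Three-way decoding (two weed ancestors plus crop) is out of scope; samples
with complex ancestry should not be run through the two-ancestor model.

### Genome bias

`genome_bias()` reports, per chromosome and group, the fraction of AIM
ancestry calls assigned to the weedy ancestor, and appends a genome-wide
`Average` row as the *unweighted mean of the chromosome rows* — the same
arithmetic as the published per-chromosome bias tables it mirrors, so the
package reproduces their averages exactly from their printed rows. A
site-weighted average is available via `weights`.

### Windowed divergence

Site FST uses the two-population Weir-Cockerham variance components with
the observed-heterozygosity term; windows combine sites as the ratio of
sums `sum(a) / sum(a+b+c)` (the weighted estimator), retaining negative
site components — truncation would bias windows upward. Windows are
half-open, anchored at position 0 of each chromosome, 500 kb wide on a
250 kb step by default, with terminal partial windows retained, matching
the convention of the variant-calling toolchains these scans are usually
run with. Site pi is the proportion of differing pairs among called
haploid alleles; the window value averages over variant sites by default
(`per_base = TRUE` divides the sum by window length instead — both
conventions exist in the field and the metadata records which was used).

With a 250 kb step every interior position lies in two 500 kb windows, so
`dual_comparison()` reports *all* windows containing a focal region's
midpoint, with genome-wide percentile ranks for both comparisons. Adaptive
introgression of a crop allele appears as a bottom-rank crop comparison
and top-rank weed comparison among the containing windows.

### Haplotype network

`extract_haplotypes()` resolves heterozygous calls by explicit parsimony:
among all phase assignments of a sample's het sites, choose the one
minimizing haplotypes not already observed among homozygote-derived
haplotypes, ties broken lexicographically. This replaces manual phasing
with a reproducible rule; samples above `max_het_sites = 8` (ambiguity
`2^k`) are excluded with a report rather than guessed at. Homozygotes
count twice by default (two identical haplotypes per diploid).

`median_joining()` iterates: build the epsilon-relaxed minimum spanning
network, form majority-consensus medians of linked triplets, add the
median that most reduces the spanning length (lexicographically smallest
on ties, with the number of co-optimal choices recorded — the "equally
parsimonious arrangements" phenomenon is surfaced, not hidden), and prune
medians of degree below three. `epsilon = 0` by default: the strictest,
smallest network. Input order cannot affect the result because all
processing is lexicographic.

`annotate_steps()` translates each mutational step through a CDS map and
flags configured resistance replacements (defaults S653N, G654E). Steps
are oriented from the reference allele where one side matches it. The
shipped map (`synthetic_als_map()`) is fully synthetic — same codon
numbering as the real resistance replacements, no real sequence — because
the true nucleotide coordinates underlying those replacements are not
asserted anywhere in this package.

### Resistance phenotypes

Injury bins follow the printed integer ranges (High 0-32, Moderate 33-67,
Susceptible 68-100), with non-integer means floored before comparison so
the inclusive printed boundaries apply unchanged. A sample whose plants
span both a resistant bin and the Susceptible bin is *Segregating* — the
published tabulation implies but never defines this rule, so it is stated
here prominently: co-occurrence of at least one Susceptible and at least
one High/Moderate plant. Percentages are rounded half-up to one decimal to
match the printed style; exact fractions are also returned.

## The simulator

`simulate_cohort()` draws independent hybrid lineages: an F1 between one
fully inbred crop-panel and one weed-panel parent, then `g` selfing
generations with Poisson crossovers placed uniformly (no interference —
the simplest model consistent with the estimators' assumptions). Ancestry
is tracked exactly as segment lists, so every downstream method can be
scored against truth. Selection is viability rejection sampling on
offspring fitness `(1+s)^d_sel * (1-bp)^d_crop`, with the acceptance bound
recomputed each generation from the current parent (selfing cannot push
dosage below 2 at a fixed-crop site). The bound is loose when many sites
still segregate, so strong background penalties need a raised `max_tries`;
penalties much above ~0.02 per allele at 300 AIMs make rejection sampling
impractically slow and are outside the simulator's intended regime.

Default scenario: 12 chromosomes of 5 Mb, 5 AIMs and 5 neutral SNPs per
Mb (300 AIMs genome-wide), 2 crossovers per chromosome per meiosis, `g =
5`, 48 lineages, panels of 10 (crop) and 11 (weed) — the sampling depth
and post-hybridization age of the study system this package was built
around, at desk scale. Marker counts are exact per chromosome by default
(`fixed_counts = TRUE`) for deterministic fixtures; Poisson counts are a
flag away.

What the simulator emulates: fixed differences between fully inbred
ancestors, selfing heterozygosity decay, linkage blocks, viability
selection at a locus and against genome-wide crop ancestry. What it does
not: residual panel polymorphism at AIMs, genotyping error (added
explicitly in tests where needed), gene flow after the F1, seed-bank
overlap of generations, mutation, and interference. Passing tests
therefore demonstrate correctness of the estimators under the model's
assumptions, not robustness to everything real data can do.

### A note on the HWE filter and inbred panels

The variant filter applies the plain conditional exact test (not mid-p),
removing sites with `p < 1e-7` — the common variant-filtering convention.
On simulated cohorts whose panels are *fully* inbred, every diverged site
shows an extreme heterozygote deficit (selfing plus a Wahlund effect), so
the demo pipeline configuration disables the HWE floor; the filter itself
is exercised on outbred-style fixtures in the test suite. Real data with
residual heterozygosity are the filter's intended target.

## Problem sizes and reproducibility

The test suite and acceptance script run everything at desk scale, chosen
so the whole suite completes in a few minutes on one core: generation
recovery uses 100 lineages per `g` in 1..6 with 300 AIMs; neutral and
penalty calibrations use 96-lineage cohorts at `g = 5` with penalties 0,
0.01 and 0.02 (a grid wide enough that the monotone response exceeds
Monte-Carlo noise at this cohort size); the selection-scan experiment uses
50 replicates of 48 lineages on 4 x 2.5 Mb chromosomes at 20 markers per
Mb, with the selected locus placed at the centre of a window-overlap
stripe so that "the window containing the locus" is well defined under
the 250 kb step. All randomness flows from a single seed; rerunning any
script or `run_pipeline()` with the same seed reproduces outputs
byte-identically (md5 digests recorded in the run manifest).

## Known limitations

- Two ancestries only, in both the supervised coefficients and the HMM.
- The generation estimator inherits the strict-selfing assumption; any
  later outcrossing biases `g_hat` downward.
- The median-joining search adds one best median per iteration (greedy);
  for the small haplotype sets of a single gene region this matches
  exhaustive Steiner enumeration (verified in tests), but it is not a
  guaranteed global optimum for large inputs.
- Windowed statistics use physical windows; no haplotype-based scans.
- The pipeline consumes externally produced Q matrices for classification;
  it never fits an admixture model itself.
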
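---
title: "Methods: allele-aware editing analysis for polyploid protoplast pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-aware editing analysis for polyploid protoplast pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyedit)
```

This vignette is the package's own account of its models and numerical
choices: what is assumed, which parameters matter, where the design was
genuinely open, and what the synthetic-data tests do and do not demonstrate
about real data.

## Coordinates, spans and gene models

Loci are parsed from the dot notation used in potato gene-structure
listings (`"chr05:9901255.9916669"`), with thousands-commas tolerated.  Two
conventions deserve emphasis:

* Coordinates are 1-based and inclusive.
* **A region's span is `end − start`**, not `end − start + 1`.  This is the
  bookkeeping under which the packaged *GWD1* locus spans 15,414 bp and the
  *DMR6-1* locus 6,398 bp, and it is applied uniformly.  Users who need the
  inclusive width of an exon can read the `width` column of a gene model,
  which *is* `end − start + 1` — the two quantities answer different
  questions and both are exposed.

Gene models validate exon lists (non-empty, inside the region,
non-overlapping after coordinate sorting) and number exons along the
strand, so the first exon of a minus-strand gene such as *DMR6-1* is the
one with the highest coordinates, as in its published listing.

## Inter-allelic variant calling

`call_variants()` operates on a *supplied* alignment (an `allele_set` of
ploidy-many gapped haplotypes plus a reference).  Producing the alignment
is the caller's job: in the motivating experiments allele resolution was
done by manual inspection of deep sequencing, which no package can
reproduce, and the synthetic generator emits alignments directly.  No
internal aligner is shipped.

Record conventions:

* one `SNP` record per alignment column where at least one haplotype
  carries a different base, with the full per-allele state string;
* contiguous gap runs collapse into single `insertion`/`deletion` records
  with the run length; the same columns gapped in *different* haplotypes
  are distinct per-haplotype events;
* `N` is a no-call and never yields a record.

SNP prevalence is summarized as SNPs per bp and as a fold change over a
user-supplied reference rate (default 0.005/bp in the demo configuration).
The reference genome itself is not shipped, so the rate is an input, and
whether the denominator should count exonic bp only or the whole target
region is left to the caller — both are computable from a gene model, and
the package deliberately does not claim one choice.

## Guide scanning and the cut-site convention

`scan_pam_sites()` enumerates every 20-nt protospacer immediately 5′ of an
NGG, on both strands, reported in plus-strand coordinates; the tests hold
it equal to a position-by-position brute-force scan.  The blunt SpCas9 cut
is taken to lie 3 bp 5′ of the PAM (between protospacer positions 17 and
18); `cut_position` reports the base left of the boundary.  The convention
matters only jointly: the expected twin-RNP deletion is the distance
between two cut boundaries, and the dual-cut detector tolerates ±2 bp
around it, so any consistent off-by-one choice would be absorbed.

Allele-consensus filtering flags guides whose protospacer+PAM footprint
overlaps any variant position; a stricter flag marks variants within the
PAM plus the PAM-proximal 12 nt of the protospacer (`seed_len`, a common
SpCas9 seed heuristic, exposed as a parameter).  The filter is monotone:
adding variants can only clear flags.

## Diagnostic primer placement

`design_primers()` enumerates forward/reverse footprints (18–25 nt by
default) that are free of inter-allelic variants in all haplotypes, lie
strictly outside the given cut sites, and produce a reference amplicon
within the requested size window (150–500 bp by default, a practical IDAA
range).  Feasibility is footprint variant-exclusion plus length windows
only — no melting-temperature or secondary-structure model; those belong
to bench-side primer tools and would add nothing to the allele-awareness
this module exists for.  Reported per-allele amplicon sizes differ when an
allele carries an indel between the primers, which is exactly the
wild-type size heterogeneity an IDAA analyst needs to know about.  When no
pair exists the function returns an empty table plus a machine-readable
report naming the constraint that failed (no clean forward footprint, no
clean reverse footprint, or no pair inside the size window).

## IDAA quantification

The motivating study quantified chromatograms with an online tool whose
algorithm is unpublished, so this module defines its own fully documented
pipeline and is validated against synthetic truth instead:

1. **Baseline**: a morphological opening (rolling minimum followed by a
   rolling maximum over the same `window_bp = 20` window), subtracted and
   clipped at zero.  The opening removes every feature narrower than the
   window while following offsets and slow drift exactly, which makes the
   correction idempotent to machine precision — a plain rolling minimum
   undershoots near peak flanks and is not.
2. **Peaks**: local maxima above `min_height_frac = 0.02` of the trace
   maximum *and* above an absolute floor `min_height = 20` RFU (the
   fractional threshold alone would happily call maxima in a noise-only
   trace).  Unresolved shoulders — adjacent maxima whose valley stays
   above 75% of the smaller apex, the signature of ±1 bp capillary
   stutter within the instrument's resolution — merge into the larger
   peak.  Apexes are refined by 3-point parabolic interpolation.
3. **Areas**: trapezoidal integrals between flanking minima, truncated
   where the signal falls to 0.5% of the apex or to the residual noise
   floor (the trace median) and never further than 3 bp from the apex,
   integrating the signal *above* that floor.  Without the truncation,
   stretches of corrected baseline between well-separated peaks (for
   example a dual-cut deletion peak 100 bp below the wild type) accrue
   into whichever peak owns them and bias molar fractions upward.
   Peaks narrower than 0.2 bp FWHM (grid-scale noise spikes) and peaks
   holding under `min_area_frac = 1%` of the detected area are discarded.
4. **Spectrum**: peaks are binned to the nearest integer size change
   relative to the wild-type peak — the peak within `size_tolerance =
   0.5` bp of the expected amplicon size (nearest apex wins; an exact tie
   goes to the larger area).  When no wild-type candidate exists but indel
   peaks do, the spectrum is anchored at the expected size with a
   wild-type fraction of zero and flagged; an empty peak table is an error
   unless the caller explicitly allows the unedited interpretation.
5. **Efficiency**: `1 − fraction(Δ = 0)` — the non-wild-type molar
   fraction of amplicons, which is the operational meaning of "editing of
   all alleles in the cell pool".  Peak area is taken as proportional to
   molar amount; no length-dependent fluorescence or PCR-bias correction
   is applied (a deliberate, documented simplification mirrored by the
   generator).

Whether sub-threshold peaks should count toward efficiency is genuinely
open; here the thresholds are explicit parameters, and the pipeline runner
uses a more sensitive setting (`min_height_frac = 0.005`,
`min_area_frac = 0.002`) chosen so that a ~1% minor-allele bin passes
while remaining several-fold above the default simulated noise.  The
practical consequence of the defaults is a small negative bias (≤ ~1.5
percentage points at low editing rates) from genuine minor bins below
threshold — visible in the parameter-recovery numbers below and accepted
as the price of noise robustness.

## Multiplex statistics and the knockout model

For two RNPs with single efficiencies $e_1, e_2$, the combined editing
under independent action is $T = 1 - (1 - e_1)(1 - e_2)$; synergy is the
observed total minus $T$.  Where figure captions in the motivating work
disagree on whether "theoretical" means this product form or the plain sum
$e_1 + e_2$, the independence formula is used throughout — it is the form
stated explicitly, and the plain sum exceeds 1 for large efficiencies —
with the sum available behind `estimator = "sum"`.  The classification
threshold (±0.02 absolute) is a package choice, exposed as a parameter;
the source experiments classified qualitatively.

The full-allelic model multiplies per-gene full-allelic rates,
$P_{\text{all}} = \prod_i p_i$, and reports the expected screening effort
$1/P_{\text{all}}$ (two genes at 10% → 1 plant in 100; three → 1 in
1,000).  Under per-allele independence within a cell,
$p = e^{\text{ploidy}}$; real within-cell correlation is unknown and is a
free simulation parameter, defaulting to independence.

Region comparisons use the pooled-variance Student t test by default (the
naming used in the source analysis) with Welch available, two-sided;
identical zero-variance inputs return $t = 0$, $p = 1$ with a flag rather
than an error.  Whether per-replicate or per-gRNA means are the proper
units is left to the caller — both are just numeric vectors here, and no
claim is made to reproduce any particular published p-value.

Rank concordance counts exact rank matches and computes Spearman's ρ with
average-rank ties, per target-region group and pooled.  P-values come from
permutations — exhaustive enumeration for groups of up to 7 guides (720
permutations at $n = 6$), where asymptotic approximations are unreliable.
Rank validation requires integer ranks within $1..n$ but tolerates ties,
because published server rankings do contain them.

## The synthetic-data generator

The generator emulates, with known truth, the study conditions the
analysis modules expect:

* **Haplotypes** — a uniform-random reference of 600 bp (the scale of an
  IDAA amplicon's neighbourhood) with per-haplotype SNPs at 0.01/bp and
  indels at 0.002/bp (geometric lengths, p = 0.5, capped at 8 bp): SNP
  density of the order seen in tetraploid elite cultivars, a few-fold
  above a diploid reference.  Indel events are mutually spaced by the
  longest indel + 2 bp so gap runs never merge and the emitted alignment
  is unambiguous; SNPs avoid indel spans but are otherwise free.  Rates
  summing above 0.3 are refused, since the no-realignment assumption
  would break.  Under these constraints `call_variants()` recovers the
  injected truth *exactly*, and that equality is a test.
* **Editing outcomes** — every allele of every cell is cut independently:
  guide $g$ with probability $e_g$; with two guides the joint-cut
  probability is $e_1 e_2 (1 + \gamma)$, clipped into its Fréchet bounds
  with a warning.  Both-cut alleles lose the inter-cut fragment; single-cut
  alleles draw a size change from the guide's spectrum; spectra default to
  a categorical over {−3, −1, +1, −2} bp with one dominant class (weights
  0.85/0.10/0.05, rotating across guides), emulating the observation that
  individual gRNAs confer characteristic indel patterns (one guide
  favouring a 3 bp deletion, another 1 bp indels).  These are
  configuration, not hard-coded biology.
* **Traces** — one Gaussian per distinct amplicon size on a 0.1 bp grid,
  area proportional to molar fraction (total 1000 area units), peak width
  σ = 0.15 bp (FWHM ≈ 0.35 bp, i.e. baseline-resolved single-bp
  differences as on a modern capillary), i.i.d. noise of 2 RFU and an
  optional sloped baseline.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate — includes PCR amplification bias and length-dependent
fluorescence (molar fractions map straight to areas, matching the
quantifier's assumption, so the pair of simplifications cancels by
construction rather than by being right), size-calibration error,
pull-up/spectral artifacts, true ±1 bp stutter products of PCR,
within-cell correlation of allele cutting, and re-cutting dynamics after
perfect repair.  Agreement on synthetic data validates the *numerics*;
on real chromatograms the molar interpretation is an approximation whose
error the package does not estimate.

Determinism: a `simulation_config` seed fully determines all three
generators (each derives an independent substream via a fixed offset), and
the pipeline derives per-stage seeds from one config seed the same way, so
reports reproduce byte for byte.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → design → quantify → stats on one config:
it scans the simulated reference, keeps allele-consensus PAM sites, picks
cut sites near one and two thirds of the region, designs a variant-avoiding
primer pair (the amplicon defines the wild-type size), quantifies each
guide singly and the pair as a multiplex, screens for the dual-cut
deletion, and writes a versioned JSON report whose every value is
re-derivable from the logged parameters.  Stage failures abort with the
stage name and move partial outputs under `failed/`.

The packaged analyses and tests run at deliberate desk scale: 10,000 cells
per simulated transformation for quantification checks (sampling error of
a pooled fraction ≈ 0.005 at four alleles per cell), 100,000 cells for the
law-of-large-numbers convergence checks (3 standard errors ≈ 0.002), 600 bp
regions, and ~1,000 random sequences for the brute-force scanner
comparison.  At these sizes the entire suite completes in well under a
minute; the statistical conclusions would not change at larger n, only the
bands would narrow.

## Known limitations

* Size-only resolution: IDAA sees amplicon lengths, not sequences; two
  different indels of equal net size share a bin, and a +0 bp substitution
  event is invisible.  Sequencing-based decomposition is out of scope.
* The primer module knows nothing about thermodynamics, and the guide
  module nothing about on-target activity scores — external scores are
  ingested as data (rank tables), never computed.
* The full-allelic model assumes independence across genes and alleles;
  chromatin state, for which the motivating experiments saw suggestive
  positional effects, is not modelled.
* `span_bp = end − start` is a convention, not a claim about biology;
  mixing it with inclusive widths from other tools is the caller's
  responsibility.
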
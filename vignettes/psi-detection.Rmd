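---
title: "Detecting pseudouridine in small RNAs: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pseudouridine in small RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiseq)
```

## The problem

Pseudouridine (Ψ) is the most abundant internal RNA modification, but it is
invisible to ordinary sequencing: it pairs like uridine and leaves no
mismatch. Three assay chemistries make it visible in small RNA libraries,
and `psiseq` implements the computational side of all three:

* **Ψ-IP** — an anti-pseudouridine antibody captures Ψ-containing RNAs;
  sequencing the bound and unbound fractions turns modification into
  differential *enrichment* of a sequence between the two fractions.
* **CMC RT-stop** — the carbodiimide CMC forms a bulky adduct specifically
  on Ψ. During library preparation the adduct blocks reverse transcriptase;
  a stopped cDNA never receives its second adapter and never amplifies, so
  Ψ-containing reads are *depleted* from the treated library relative to a
  mock-treated library prepared from the same RNA.
* **CMC/Mn²⁺ readthrough** — reverse transcription of CMC-treated RNA in
  Mn²⁺-containing buffer reads through the adduct, but errs while doing so:
  the Ψ position appears in the read as a *mismatch or a deletion*. This
  converts the modification into a position-level signal.

The three signals are statistically different objects — a per-sequence
enrichment, a per-sequence depletion, and a per-position error ratio — and
the package keeps them in three layers (the `nb_wald_test()` engine for the
first two, `call_mismatch_sites()` for the third) joined by
`call_psi_features()`.

Because the interesting biology concerns *classes* of small RNA, a fourth
layer classifies sequences: tRNA fragments by their anchoring on the parent
tRNA (`classify_trf()`), transposon siRNAs by family and size class
(`aggregate_te_families()`), piRNA-like reads by repeat category and
cluster (`categorize_repeats()`), plus Argonaute preference
(`ago_preference()`) and terminal nucleotide bias (`terminal_nt_bias()`).

## Why position 55 and UNUAR matter

Two enzyme systems give clean internal controls. PUS7 modifies the central
U of the UNUAR motif (U-N-Ψ-A-purine); PUS10 modifies the near-universal
T-loop uridine at canonical position 55 of tRNAs. On a standard 76-nt
CCA-tailed tRNA, position 55 lies exactly 22 nt upstream of the 3′ end, so
among 3′-tRFs (fragments ending at the CCA tail) only those of length ≥ 22
contain Ψ-55:

```{r geometry}
cfg <- sim_config(seed = 1)
built <- build_reference(cfg)
trna <- built$reference$annotations[
  built$reference$annotations$class == "tRNA", ][1, ]
sapply(c(20, 21, 22, 23), function(L) {
  a <- data.frame(ref = trna$ref, start = trna$end - L, strand = "+",
                  n_mm = 0L, n_del = 0L)
  a$sequence <- substr(built$reference$sequences[[trna$ref]],
                       trna$end - L + 1, trna$end)
  classify_trf(a, trna)$spans_psi55
})
```

This geometry is the package's sharpest end-to-end check: in a simulation
where the only modification is Ψ-55, the CMC arm must deplete exactly the
≥ 22 nt 3′-tRFs, and the modal length of significantly depleted fragments
must come out at 22 nt. `trf_depletion_study()` runs that entire chain
(FASTQ emission → trimming → collapsing → alignment → paired NB test →
tRF classification → size distribution).

## The synthetic-data generator

`build_reference()` constructs loci-scale references standing in for a
genome: one 1.8-kb rRNA locus with twelve DKC1-class sites, eight 76-nt
tRNAs (all with Ψ-55; four carry a planted UNUAR motif away from the 3′
half, so PUS7 and PUS10 signals never share a fragment), 24 miRNA
precursors (ten with a DKC1 site in the mature arm), six TE families with
three ~2%-diverged copies each (four families carry Ψ of unassigned enzyme
class), two piRNA-cluster intervals, and snoRNA/snRNA loci used as the
structural-RNA exclusion set. Mutant genotypes (`pus7`, `pus10`, `dkc1`)
remove exactly their enzyme's truth records while leaving sequences
untouched, as in a synthase knockout.

`simulate_pool()` draws species with class-appropriate lengths (miRNA
20–22, tRFs 18–30 including every 3′-CCA suffix length, TE siRNA in the
20–22 and 23–25 classes, piRNA-like 26–31, rRNA fragments 18–30) and
log-normal(0, 1) abundances. The generator's default study conditions —
capture probabilities 0.8 (Ψ) vs 0.05 (background), per-Ψ RT-stop
probability 0.8, Mn²⁺ mismatch/deletion rates 0.3/0.1 per read, 2×10⁵
reads per library, three library pairs — are fixed once in `sim_config()`
and used unchanged by the packaged studies.

Mechanisms are modeled at the level the chemistry acts:

* capture is a per-read Bernoulli draw, so bound + unbound conserve the
  pool draw exactly;
* the RT stop is a per-read *dropout* with probability $1-(1-\alpha)^k$ for
  a read spanning $k$ sites (a stopped cDNA is lost, not truncated, because
  only one adapter is ligated before CMC treatment);
* Mn²⁺ readthrough substitutes (probability $m$) or deletes (probability
  $d$) each Ψ position per read, independently.

What the generator deliberately does **not** emulate: ligation bias, PCR
duplicates, UMI collisions beyond the kit's 4-nt random ends, partial CMC
conversion heterogeneity between molecules of the same species, and
Ψ on antisense strands (planted truth lives on the annotated strand; the
antisense strand of a duplex is a different molecule). Passing tests
therefore demonstrate that the *pipeline logic* is correct under the
stated mechanisms, not that real libraries are free of these nuisances.

Reproducibility: every sample derives its own RNG stream from
`(master seed, sample label)`, so any single library can be regenerated
without replaying the whole study, and identical configurations produce
byte-identical FASTQ.

## Preprocessing and alignment

Adapter trimming removes the longest read suffix matching a prefix of the
3′ adapter (minimum overlap 6; one mismatch tolerated from overlap 10 —
conventional values, since the protocols name tools rather than
parameters). The NextFlex dialect then strips four random nucleotides from
both insert ends; NEB adds none. Length windows are per-analysis presets
(`rrna` 15–30, `te` 18–30, `mirna` 20–25, `mn2` 18–42, `mouse` 14–44 nt
with the Q20-over-90% rule). The plant presets are length-only because no
quality rule is stated for them; the quality dimension exists in simulated
data (constant Phred 35, errored bases at Phred 20) so the mouse filter is
genuinely exercised.

References here are loci, not genomes, so the aligner can afford to be
exhaustive: a banded dynamic program (compiled, via Rcpp) scans every
window start on both strands and reports *all* placements within the edit
budget (≤ 3 substitutions, ≤ 2 reference deletions; insertions are not
modeled because the chemistry does not produce them). Deletions are
internal and left-aligned; within a homopolymer run the deleted base is
not identifiable, so downstream site matching allows a 2-nt localization
window — the same tolerance class as the metaplot's "minimum at offset
0 ± 1" property. The test suite holds the aligner to an independent
exhaustive-scan oracle on 200 random mutated reads.

Multimapping follows the analysis arm: `all` (TE-family aggregation counts
a read once per family), `unique_only` (metaplots; also the reading we
adopt for "a single mapping event per read", with `best_random` available
as the alternative), or `best_random`.

## The paired enrichment engine

Counts are normalized with median-of-ratios size factors and tested per
feature with a negative-binomial log-linear model containing a pair
covariate (treated/mock or bound/unbound libraries prepared from the same
RNA) and a condition coefficient, using `stats::glm` with the
`MASS::negative.binomial` family and fixed per-feature dispersion.
Dispersion is estimated by the method of moments on normalized counts
within conditions and shrunk 50/50 in log space toward a loess
mean–dispersion trend — a deliberate simplification of the reference
tool's empirical-Bayes machinery, documented as such.

Three numerical choices matter for calibration and finiteness:

* the Wald SE comes from the model-based covariance
  (`summary(fit, dispersion = 1)`); letting `summary.glm` estimate a
  quasi-dispersion from ~2 residual df destroys calibration;
* log-scale moment dispersions are corrected for the small-sample bias
  $\psi(\nu/2)-\log(\nu/2)$ of a log variance on $\nu$ df before trend
  fitting and shrinkage;
* when the dispersion is estimated (not supplied), the Wald statistic is
  referred to a t distribution with $2\nu$ degrees of freedom — residual
  df plus an equal prior contribution from the trend, the moderated-df
  convention of small-sample count frameworks. With these choices the
  null p < 0.05 fraction on 1000-feature simulations sits at 0.04–0.05.

The reported `log2fc` is the moment estimate with a 0.5 normalized-count
pseudocount on both sides, so it is always finite even under complete
separation; the raw GLM coefficient is kept in `log2fc_mle`. The
`>10` mean-raw-count filter (strict) is applied *before* testing, so
filtered features never enter the BH denominator; the piRNA-cluster
analysis instead requires a mean of ≥ 100 raw reads on the relevant arm.
BH correction is applied per assay arm and feature level, never pooled.

One normalization caveat is worth spelling out because it decides a whole
study: median-of-ratios assumes most features are unchanged. In the
3′-tRF depletion study, fragment lengths are uniform over 18–30 nt, so
*most* fragments (≥ 22 nt) genuinely lose ~90% of their reads and the
median ratio sits inside the depleted majority, absorbing the signal. In
the generator's library model the treated fraction is an equal-size pool
draw minus absolute per-read loss, so that study passes unit size factors
instead. The general recovery study keeps median-of-ratios, where non-Ψ
species form the anchor majority.

## The mismatch site caller

`mismatch_profile()` is a pileup: per reference position, reads covering
it, reads substituted there, reads with a deletion there (a deleted
position still counts as covered — deletions consume reference). The
caller evaluates every position with ≥ 5 treated reads and calls a site
when the pooled (mismatch+deletion)/coverage ratio is at least 1.5-fold
the mock ratio; the mock ratio uses a $(x+0.5)/(n+1)$ pseudocount because
nothing is stated for zero-mismatch mock positions. Mismatches and
deletions are pooled for the ratio and also tallied separately. Both the
per-position reading and a per-feature reading (fraction of a feature's
reads carrying any edit, `call_mismatch_features()`) are provided, since
the published criterion is phrased per miRNA.

A limitation the user should know: the 5-read/1.5-fold rule has no guard
against *matched background noise*. With a background error rate of 10⁻³
at 500× coverage, both libraries expect ~0.5 errors per position, and a
position with a couple of Poisson errors in the treated library and none
in the mock clears the 1.5-fold ratio regardless of depth. The packaged
recovery study (`mn2_site_study()`) therefore isolates the Mn²⁺ chemistry
with background error off (an exposed argument); with it on, per-position
calls at moderate coverage need either deeper mock coverage or a
count-based test, which the published rule does not include.

## Study sizes and runtime

The packaged studies are sized for a single CPU: the tRF depletion study
uses 10⁵ reads per library × 6 libraries, the recovery and genotype
studies 2×10⁵ reads per library at count level (FASTQ emission and
re-parsing add nothing to a count-level question), and the Mn²⁺ study
2.5×10⁴ reads giving > 500× at every planted site. Each completes in
well under a minute except the FASTQ-level tRF study (~15 s).

## Known limitations

* The NB engine has no outlier handling and no LFC shrinkage; with three
  pairs, a single wild library can dominate a feature.
* The aligner is exhaustive and loci-scale by design; it is not a genome
  aligner and makes no attempt at FM-index scaling.
* Truth-aware metrics (sensitivity, FPR) exist only for simulated data;
  on user data the package reports calls and evidence classes only.
* The Ψ-IP model treats capture as independent Bernoulli per read; avidity
  and multi-Ψ cooperativity are not modeled, so IP enrichment in real
  data may scale with Ψ count in ways the simulation does not predict.
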
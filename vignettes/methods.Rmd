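---
title: "Classifying structural-variant candidates against random genomic regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying structural-variant candidates against random genomic regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Benchmarking structural-variant (SV) callers needs call sets whose entries are
trustworthy beyond the say-so of any single caller.  `svarbiter` builds such
sets by measuring, for every candidate deletion or insertion, how strongly the
aligned reads around it deviate from what random places in the genome look
like — across several sequencing datasets at once — and keeping candidates
whose deviation is extreme in at least `k` of them.

The central design choice is *one-class* classification.  Two-class models
need a representative sample of true SVs to train on, and no such unbiased
sample exists: curated SV sets are skewed toward mid-size deletions in easy
sequence.  Random genomic coordinates, by contrast, are cheap, unbiased, and
almost never sit on an SV breakpoint, so they make a clean "normal" class.
Anything far from that class, in the right annotation directions, is evidence
of an SV.

## Five windows and their annotations

Every candidate interval `[start, end)` is partitioned into five windows: the
left flank `L`, the left-inner window `LM`, the SV interval `M`, the
right-inner window `RM`, and the right flank `R` (`partition_site()`).  Flanks
default to 100 bp — the order of a short-read length, so breakpoint-crossing
reads fall inside them; the value is configurable and `LM`/`RM` are capped at
half the SV length so they never overlap.  All internal coordinates are
0-based half-open; file readers and writers convert at the boundary.

Per window and dataset, `annotate_sites()` computes from the BAM:

* mean aligned-base depth (`*_Cov`) — deletions halve (het) or empty (hom)
  the inner windows; a read counts in every window its aligned span overlaps
  by at least 1 bp, deletion (`D`) CIGAR segments contribute no depth;
* the fraction of reads soft/hard-clipped by at least 5 bases
  (`*_SoftClip`) — reads crossing a breakpoint map only partially;
* mean mapping quality (`*_MapQ`);
* for paired data: insert mean/sd (`*_InsertMean`, `*_InsertSd`), where the
  insert is the end-to-end distance of a proper pair (both read lengths plus
  the gap, negative for overlapping mates — the SAM TLEN of an FR pair),
  counted once via the leftmost mate; the discordant fraction (`*_Discord`:
  mate on another chromosome, same-strand orientation, or insert beyond
  mean + 4 sd of the dataset's proper pairs); and the mate-unmapped fraction
  (`*_MateUnmapped`), a novel-insertion signal;
* for long single-end reads: per-read deleted and inserted bases per read
  base (`*_DelRate`, `*_InsRate`), and their normalized difference
  `M_DelInsDiff`.  Long reads carry high background indel error, so both
  rates are recentered by baseline means over random regions; the defaults
  (0.0428 deleted, 0.0948 inserted bases per base) suit PacBio-class data and
  `run_pipeline()` re-estimates them from the training regions;
* reference/sample context over `M`: GC fraction (N bases excluded),
  coverage fractions by RepeatMasker class, het/hom SNP counts, SV length.

The *one-class* annotation subset deliberately excludes the context columns
and mapping quality: an odd GC fraction or low MAPQ marks a difficult region,
not an SV, and context is not technology-specific, so it cannot contribute to
a multi-technology evidence rule.  Those columns remain available in the
`clustering` and `full` subsets, where they help separate *kinds* of sites.
Per technology the one-class subset is: paired-end — inner-window depths,
flank clipping, flank insert mean/sd, flank discordance and mate-unmapped
fractions (13 columns); long reads — inner-window depths, flank clipping, and
`M_DelInsDiff` (6 columns).

Duplicate-flagged, QC-fail, secondary and supplementary alignments are
excluded everywhere; MAPQ-0 reads are kept in denominators (low mapping
quality is itself a signal worth seeing in the clustering columns).

## Transform and standardization

Annotations span wildly different scales and are heavy-tailed, so each is
passed through the inverse hyperbolic sine,

\[ y = \sinh^{-1}(x) = \log_e\!\left[x + \sqrt{x^2 + 1}\right], \]

which behaves like `log(2x)` for large `x` but is defined at zero and for
negative values (needed for the recentered long-read rates), then
standardized: \(z = (y - \mu)/\sigma\) with \(\mu, \sigma\) computed **on the
training random regions only** and frozen (`fit_transform_model()` /
`apply_transform()`).  Anchoring to the training set keeps a candidate's
score independent of whatever batch it arrives in.  Constant training columns
carry no distance information and are dropped with a warning.  Masked cells
(no usable evidence, e.g. insert statistics in a region without proper pairs)
are imputed with 0 — the standardized training mean, the neutral choice under
an L1 distance from the training centroid — and flagged.  When several
datasets feed one combined model, each dataset is standardized against its
own training table first and the columns concatenated.

## The L1 one-class classifier

Let \(M\) be the column-mean vector of the \(n\) transformed training
regions and \(d_i\) their L1 (Manhattan) distances from \(M\); L1 is less
sensitive than Euclidean distance to the occasional wild training region.
The acceptance region at level \(p\) is the multidimensional rhombus
\(\{x : \lVert x - M\rVert_1 \le t_p\}\), where \(t_p\) is the smallest
training distance with at least \(p\,n\) training distances at or below it
(an order statistic; no interpolation).  A new site is called an SV when its
distance strictly exceeds \(t_p\) — ties resolve to non-SV, the conservative
side.  By construction exactly \(\lceil p n \rceil / n\) of the training set
is inside its own boundary, which the tests assert.

The graded score is
\(\rho = \#\{i : d_i < d\}/n\),
the fraction of training regions strictly closer to the centroid than the
candidate.  For exchangeable non-SV sites \(\rho\) is uniform on \([0,1]\) up
to the \(1/n\) granularity, so \(P(\rho > p) \approx 1 - p\) — the
calibration the acceptance suite checks on held-out simulated regions
(about 1% above 0.99).  Scores are stratified into the tiers
0.68 / 0.9 / 0.97 / 0.99 / 0.997 / 0.999 (half-open bins, top bin closed).

## The one-class SVM variant

As a robustness check, `fit_svm_model()` trains Schölkopf-style one-class
SVMs.  Each annotation is first given a *deviation direction* — depth below
normal is deviant for deletions; clipping, discordance, mate-unmapped and
insert statistics above normal are deviant; the long-read del−ins difference
is two-sided.  The directional deviation is mapped through the training
empirical CDF as \(u = 1 - F(v)\) (strict-less CDF), so \(u \in (0,1]\) on
training values and strong deviants land near 0; a linear boundary then
suits the one-sided geometry.  One SVM is trained per \(\nu\) in
\(\{0.01, 0.02, 0.05, 0.1, 0.2, 0.32, 0.5\}\) — \(\nu\) approximately fixes
the fraction of training left outside, i.e. a training true-negative rate of
\(1-\nu\); the grid's complements line up with the stratification tiers.
Because boundaries at different \(\nu\) can intersect, the score is the
smallest training true-negative rate at which the site is still inside:
\(1 - \max\{\nu : \text{inside at } \nu\}\), with sites outside every
boundary scoring 1 (maximally SV-like) and sites inside even the tightest
boundary scoring \(1 - \nu_{\max}\).  This makes the SVM score directly
comparable to \(\rho\): both classifiers call "SV" above the same threshold
\(p\), and the acceptance suite checks they agree on at least 80% of
simulated sites.  The L1 classifier remains the primary method; the SVM is
the cross-check.

## Ensemble, pre-filters, clustering

Per-dataset calls are combined with a *k-of-n* rule: a site is an SV when at
least `k` datasets (default 3) call it one.  The single number stratified is
the k-th largest per-dataset \(\rho\) — it exceeds \(p\) exactly when at
least `k` datasets do, so one score reproduces the vote at every threshold.
Before stratification, sites with flank coverage above 300 in **both** flanks
(likely duplicated sequence) or mean flank MAPQ below 30 in **either** flank
(unreliable placement) are flagged by `prefilter_sites()`; the coverage
threshold is about 1.5 times a deep (200x) dataset's mean and both thresholds
are configurable.

For exploration, `ward_cluster()` applies Ward linkage directly to the L1
distances.  Ward formally assumes squared Euclidean input; applying the
Lance–Williams update to unsquared L1 dissimilarities (the `ward.D`
convention of `stats::hclust`) is the established practice this package
follows deliberately, because the combination separates site classes well in
this annotation space.  `cut_tree()` numbers clusters left-to-right in the
dendrogram (tighter subtree left, ties to the smallest member index), and
`mds_embedding()` provides a classical (Torgerson) MDS view, default k = 3,
with a fixed sign convention so embeddings are reproducible.

## The simulators, and what they do and do not show

Two generators make every stage testable without external data.

`simulate_genome()` + `simulate_reads()` build a random reference (GC 0.41),
plant non-overlapping homozygous/heterozygous deletions and insertions, and
sample reads from the two donor haplotypes, computing each read's reference
alignment *analytically* from the donor-to-reference segment map — no
aligner, so truth is exact and deterministic given the seed.  Reads crossing
deleted sequence acquire spanning `D` CIGARs (up to 30 bp for short reads,
mimicking aligner limits; unlimited for long reads) or soft clips; pairs
spanning deletions get stretched inserts and lose the proper-pair flag beyond
mean + 4 sd, as an aligner would flag them; reads fully inside inserted
sequence become unmapped mates.  Long reads receive per-base indel
sequencing errors at configurable rates so the baseline normalization is
exercised.  Fixture scale: two contigs totalling 140 kb, two paired datasets
(30x/100 bp and 20x/150 bp) and one long dataset (12x, 0.8–2.5 kb), which
keeps the full pipeline under two minutes.

`simulate_annotation_table()` draws per-site annotation vectors directly
from a parametric sketch of the same signals (depth scaled by 1 / 0.5 / ~0
for random / het / hom sites with window-size-dependent sampling noise,
binomial clipping and discordance fractions, insert moments with their
sampling distributions).  This is the route for experiments at the published
scale — 4000 training regions with log-uniform sizes 50–997527 bp and a deep
200x short-read dataset — which no desk-size genome can hold.  Draws are
independent across sites given the class, so training and held-out tables
are exchangeable and the \(\rho\) calibration holds by construction; that is
precisely what it is used to demonstrate, plus group separation for
clustering.

What passing these tests shows: the arithmetic of every annotation (checked
cell-by-cell against naive SAM-text oracles), the calibration and
training-coverage guarantees of the classifier, the zygosity ordering of
scores (hom > het > random, via the full read-level pipeline on 50 + 50 + 100
sites over three datasets), and the internal consistency of ensemble,
pre-filter and stratification rules.  What it does not show: behavior under
alignment artifacts, repeat-driven mismapping, GC-dependent coverage waves,
chimeric reads or imprecise breakpoints — none of which the simulators
emulate.  Results on real data depend on those, which is why the pre-filters
and the multi-technology ensemble exist.

## Numerical choices and degenerate inputs

* Empirical quantiles are order statistics (no interpolation); \(\rho\) uses
  strictly-closer counting and classification uses strict `>`, so boundary
  ties resolve toward non-SV.
* Reciprocal-overlap matching (`reciprocal_overlap_match()`) uses an
  inclusive boundary (overlap ≥ fraction × both lengths); among multiple
  matches the largest overlap wins, ties to the smallest start.
  Deduplication (`deduplicate_calls()`) discards *both* members of a
  within-set overlap (such pairs may be compound-het or imprecise calls) and
  resolves cross-set overlaps by set priority.
* Random-region sampling rejects placements overlapping excluded intervals,
  capped at 1000 attempts per region, then errors loudly.
* Zero-width windows (flanks truncated at contig ends, inner windows of
  1-bp sites) yield masked cells, not errors; sites whose partition fails
  entirely yield fully masked, flagged rows.
* SNP parsing keeps only single-base REF/first-ALT records; `0/1`, `1/0` and
  phased variants map to het, `1/1` to hom; genotypes referencing a second
  ALT are ignored (multi-allelic records contribute their first ALT only).
* The spannable-deletion cap (30 bp) for simulated short reads, `min_clip`
  = 5 bases, and the mean + 4 sd discordance cutoff estimated from 1000
  sampled proper pairs are package defaults, stated here because no standard
  exists; all are arguments.

## Known limitations

Only deletions and insertions are modelled — no inversions, duplications or
translocations.  The `full` annotation set is the closure of all defined
metrics over the five windows; real studies may add caller-specific columns.
CRAM input and symbolic-allele VCF candidates are out of scope (candidates
arrive as BED-like lists).  The one-class model inherits the blind spots of
its training class: regions that are *systematically* unlike random draws —
but for reasons other than an SV — can only be caught by the pre-filters and
manual review.
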
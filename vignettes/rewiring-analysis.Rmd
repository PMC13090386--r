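---
title: "Models and methods: variant-driven promoter-enhancer rewiring analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: variant-driven promoter-enhancer rewiring analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewirekit)
```

`rewirekit` analyses the intersection of two patient-level data modalities:
per-patient sets of statistically significant promoter-anchored chromatin
interactions (promoter capture Hi-C), and matched germline variant calls.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data validation does and does not show.

## Coordinate conventions and input QC

All internal coordinates are 0-based half-open. VCF input (1-based) is
converted on read: a SNV at POS = 100 occupies `[99, 100)`; an indel with a
reference allele of length *k* occupies the left-anchored footprint
`[POS-1, POS-1+k)`. BED-family input is native. Overlap is plain half-open
set intersection, implemented on `GenomicRanges` and property-tested
against a quadratic scan. A single convention end to end is the cheapest
insurance against off-by-one errors in the variant-to-anchor assignment,
which every downstream count inherits.

Multi-allelic records are rejected by default (`multiallelic = "reject"`),
matching the upstream variant-calling convention for this kind of cohort;
`"split"` re-emits one biallelic record per alternative allele with
per-allele dosages. Variants with MAF at or above 10% are dropped at read
time: the pipeline targets rare and moderately rare regulatory variation,
and carriers are defined by alt dosage ≥ 1 (rare variants are expected
heterozygous; homozygotes are treated as carriers, not excluded).

Interaction QC keeps a row iff `support_pairs >= 5`, Bonferroni-adjusted
`p < 0.05`, the pair is cis, the anchor-midpoint distance is `< 5 Mb`, and
both anchor fragments are `< 7,500 bp`. Boundary semantics are asymmetric
on purpose — support keeps at equality, distance/fragment drop at equality,
p keeps strictly below — because those are the stated filter definitions of
the interaction-calling protocol this package consumes. Two choices the
protocol leaves open are fixed here and exposed as configuration: the 5 Mb
rule is applied to anchor *midpoints* (nearest-edge distance would differ
by at most one fragment length, well under the threshold scale), and the
fragment length is taken to be the anchor width `end - start`, since
anchors are restriction fragments and a separate length field would be
redundant. Dropped rows are attributed to their *first* failing rule in the
fixed order support, p, trans, distance, fragment, so QC reports are
reproducible partitions rather than overlapping tallies.

## Rewiring events

For a variant with carrier set $C$ and an interaction present (after QC) in
patient set $S$, with patient universe $P$:

* $S \subseteq C$: gain-of-interaction (GoI), **concordant** — the
  interaction exists exclusively in carriers;
* $S \subseteq P \setminus C$: loss-of-interaction (LoI), **concordant**;
* otherwise **discordant**, with direction by the majority presence rate
  ($|S \cap C|/|C| \ge |S \cap (P\setminus C)|/|P \setminus C|$ calls GoI;
  the tie goes to GoI).

"Rewired exclusively in carriers" is formalised as *subset* semantics, not
set equality: an interaction detected in two of three carriers and no
non-carrier is still exclusive to carriers, and detection dropout makes
exact presence/carrier equality rare in capture data. Equality semantics
remain available (`semantics = "equality"`) for sensitivity analyses.
Variants carried by nobody or by everybody provide no genotype contrast and
yield no event. The classifier is total on its domain and its three
outcomes are mutually exclusive; the test suite verifies this by exhaustive
enumeration of all (carrier, presence) set pairs for small cohorts.

Events are enumerated per (variant × interaction × component), where the
component records which anchor the variant hits; a variant overlapping both
anchors of one interaction yields one promoter-component and one
enhancer-component event, because all downstream summaries separate the two
components. Cohort specificity is determined by the carriers alone
(case-specific, control-specific, or shared).

Association statistics use the two-tailed Fisher's exact test
(`stats::fisher.test`, hypergeometric point-probability rule) but report
the *sample cross-product* odds ratio $ad/bc$ rather than the conditional
MLE; the cross-product is the convention used for the published event-count
tables this package reproduces, and it is exactly testable in rational
arithmetic. Degenerate tables are flagged (`Inf` when $bc = 0 < ad$, `NaN`
for 0/0) instead of silently adjusted.

## Motif impact

A PWM of length $L$ scores a word by summing per-position log-odds
weights. The motif p-value of a score $s$ is
$p(s) = \Pr(\text{score of a random background word} \ge s)$, computed
*exactly* by dynamic programming: on construction, weights are snapped to a
fixed-point grid (default resolution $10^{-4}$), and the score distribution
is the convolution of the per-position four-point integer distributions
under the background. Because scoring and the distribution use the same
snapped matrix, p-values are exact for the represented matrix and
independent of floating-point summation order; off-grid query scores take
the next grid point up, so the tail at any achievable score is exact. The
suite checks agreement with exhaustive $4^L$ enumeration to $10^{-9}$.

Variant annotation scans every motif placement overlapping the variant base
in a window of length $2L-1$ on both strands, and takes the best (minimum)
hit p-value for the reference and the alternative windows. The impact is
$\log_2(p_{ref}/p_{alt})$; gain-of-motif requires the alternative allele to
be a valid hit ($p_{alt} \le 5\times10^{-4}$, the conventional hit
threshold) with at least a $2^2 = 4$-fold p-value improvement
(`fc_min = 2`, configurable — the fold-change cutoff is not fixed by any
published convention for this design, so the default follows the common
practice of requiring a 4-fold change), and loss-of-motif symmetrically on
the reference allele. Matrix files are plain-text PWM or count (PCM)
dialects; counts convert to log2-odds with a background-proportional
pseudocount of 1. Indel windows are supported as an extension (equal-length
flanked windows around the edited locus).

## Allelic imbalance

Interaction-spanning reads over a heterozygous site give allele counts
$(n_{ref}, n_{alt})$. After QC (genotype quality ≥ 50, depth ≥ 10, ≥ 5
reads per allele, all inclusive), the null of no allele-specific contact
is modelled conditionally on the total $n = n_{ref}+n_{alt}$: the
alternative count follows a beta-binomial with mean ½ and a single global
intra-class correlation $\rho$, estimated by method of moments from the
excess variance of alt fractions across sites
($\mathbb{E}[(f-\tfrac12)^2] = (1+(n-1)\rho)/(4n)$, pooled, clipped to
$[0, 0.5]$). This conditional model is a deliberate simplification of
read-count imbalance models that fit full coverage distributions: it
captures the same allelic-ratio null, needs no coverage model, and is
exactly testable against Monte-Carlo draws. At $\rho = 0$ it *is* the exact
binomial test, which the suite asserts in closed form
($p_{\to alt}(0, 20) = 2^{-20}$).

One-tailed p-values include the observed point mass (standard exact-test
convention); the two-tailed p doubles the smaller tail and caps at 1. The
doubling is conservative for asymmetric discrete tails; the empirical size
at $\alpha = 0.05$ over $10^4$ null draws sits near 0.04.

Gene-level aggregation uses the Mudholkar–George logit method
($T = -\sum \log\frac{p_i}{1-p_i}$ referred to a scaled $t_{5k+4}$): first
across the SNVs of a gene within one patient, then across patients, then
Benjamini–Hochberg over genes. A single p-value passes through unchanged.
p-values of exactly 0 or 1 (the doubling cap produces 1 routinely) are
clamped to the open unit interval with a warning; clamped balanced sites
push combined nulls towards 1, which is conservative and keeps the all-null
false-discovery rate below nominal, as the simulation tests confirm.
Output order is by gene ID, making results independent of input order.

## Cell-type enrichment

A transcript is *altered* in a cell type if (a) it is a gene of a
concordant event's promoter anchor, (b) it is expressed there (mean
expression above a floor, default 0 — no published cutoff exists, so the
floor is explicit configuration), and (c) at least one TF whose motif the
event's variant alters is expressed there. An optional DE prefilter
(two-sided Wilcoxon rank-sum of each cell type against the rest, BH within
cell type, higher in-group median) can restrict both the altered set and
the expressed universe.

Events are stratified by MAF into half-open bins: rare `[0, 2%)`,
moderately rare `[2%, 4%)` and common `[4%, 10%)`. The upper stratum is
stated in its source only as "common (5%)", which is not an interval; the
implementation closes the gap to the upstream 10% filter so that the strata
partition all events, and leaves the boundary configurable.

Test 1 (promoter events) and test 2 (enhancer events, concordant and
discordant classes separately) compare, per cell type and stratum, altered
vs expressed-but-not-altered gene counts between cohorts by two-tailed
Fisher's exact test. The BH family is across cell types within each
(stratum × component × class), mirroring how such per-test FDR results are
usually presented. The denominator ("expressed genes in the cell type") is
an explicit configuration choice recorded in the output columns. Because
altered sets are subsets of a shared expressed universe, the Fisher
sampling model is only an approximation to some data-generating processes;
the suite therefore checks calibration under a null in which alteration is
independent per universe gene (empirical size ≈ 0.04 at $\alpha = 0.05$)
and checks conservatism (rate ≤ nominal) on full no-effect synthetic
cohorts.

Network summaries (node count, unique undirected edge count, average degree
$2|E|/|V|$) support degree reporting for prioritised gene sets.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the pipeline targets: 8 case
and 8 control patients; an abstract single-chromosome genome with ~1 kb
promoters and ~800 bp enhancer fragments (no sequence needed except tiny
embedded words for motif tests); 2,000 rare variants whose population MAFs
follow configurable stratum proportions (default 50/30/20 across
rare/moderately rare/common); a background interactome present in every
patient; and planted structure with exact truth tables:

* concordant GoI events — carriers sampled within the case group (1–3
  patients, i.e. heterozygous carriers), interaction presence set equal to
  the carriers; concordant LoI events symmetrically in the control group
  with presence equal to the complement; discordant events with presence
  spanning both genotype classes;
* planted anchors and variants live in reserved regions that background
  interactions and variants never touch, so recovery is noiseless *by
  construction* — this is what lets the suite assert sensitivity =
  specificity = 1 rather than approximate bounds;
* overdispersed allelic counts (beta-binomial, default $\rho = 0.05$,
  planted alt fraction 0.8 at 10 imbalanced genes vs 200 null genes,
  roughly 40–60x coverage) resembling deep capture data;
* a mean-expression profile in which the TFs of case events are expressed
  only in one target cell type, planting a case burden there; a no-effect
  mode (`burden = list(enabled = FALSE)`, `expressed_fraction < 1`) for
  null calibration; and optional per-cell log-normal matrices with planted
  2-fold DE effects for the DE-flagging test.

A single root seed drives fixed per-stage offsets, so stages can be
regenerated in isolation and the whole bundle — including every written
file — is byte-identical across runs with the same seed.

What passing these tests shows: the event algebra, the exact tests, the
aggregation and the FDR machinery are correct on data satisfying their
assumptions. What it does not show: robustness to detection dropout in the
interactomes (presence sets are noiseless here), reference-mapping bias in
allele counts, LD structure among variants, or realistic single-cell noise
— real cohorts violate all of these to some degree, and conclusions there
lean on the concordant/discordant and case/control contrasts rather than on
the absolute counts.

## Problem sizes and runtime choices

The shipped validation uses a 16-patient, 2,000-variant cohort with 70
planted concordant events for recovery; 100 random PWMs up to length 8
against exhaustive enumeration; $10^4$ null draws for test size; and 500
reduced-size replicates (60 genes, 40 variants) for the null discovery
rate. These sizes were chosen so the full statistical argument — exactness,
calibration, recovery — closes in a few minutes on a single core; all of
them scale up through `sim_config()` without code changes.

## Known limitations

* The allelic-imbalance model conditions on total coverage; sites whose
  coverage itself is allele-dependent (strong mapping bias) are outside the
  model.
* The concordance classifier is presence/absence only; quantitative
  fine-tuning of interaction strength is explicitly out of scope.
* Interaction anchors are resolved to annotated regions by exact coordinate
  identity, which assumes interactions and region annotations derive from
  the same fragment map (true for the generator and for fragment-based
  pipelines).
* Fisher's exact test is conservative for the small per-stratum tables that
  sparse cohorts produce; empty strata are omitted rather than padded.
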
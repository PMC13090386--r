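# rewirekit

Rare regulatory variants can rewire individual promoter–enhancer contacts.
When patient-specific promoter-capture Hi-C interactomes are matched with
whole-genome sequencing in a case/control cohort (e.g. bicuspid vs
tricuspid aortic valve patients), every heterozygous rare variant
(MAF < 10%) that falls inside an interacting promoter or
promoter-interacting region (PIR, treated as an enhancer) defines a
candidate *rewiring event*. `rewirekit` implements the downstream analysis
of such a design as a tested R pipeline:

- **Event classification.** For a variant with carrier set *C* and an
  interaction observed in patient set *S* (out of all patients *P*): the
  event is a concordant **gain-of-interaction** (GoI) when *S ⊆ C*, a
  concordant **loss-of-interaction** (LoI) when *S ⊆ P \ C*, and
  **discordant** otherwise (direction by the majority presence rate).
  Events are labelled case/control-specific by their carriers and
  summarised per component (promoter vs enhancer), with two-tailed
  Fisher's exact tests on tier-gene vs housekeeping-gene contingency
  tables (the odds ratio is the sample cross-product *ad/bc*).
- **Interaction QC.** Support ≥ 5 read pairs, Bonferroni-adjusted
  *p* < 0.05, cis only, anchor-midpoint distance < 5 Mb, restriction
  fragments < 7,500 bp, with first-failing-rule drop accounting.
- **Motif impact.** Exact PWM motif p-values
  *p(s) = Pr(background word scores ≥ s)* by dynamic programming over a
  fixed-point score grid; per-variant best-hit p-values on both strands
  for the reference and alternative windows; impact
  *log2(p_ref / p_alt)* with gain-/loss-of-motif calls at a hit threshold
  of 5·10⁻⁴, and per-TF-family burden tests.
- **Allelic imbalance.** Per-SNV beta-binomial test of interaction-read
  allele counts (conditional on total coverage, mean ½, one global
  method-of-moments overdispersion), doubled one-tailed p-values, and
  two-stage Mudholkar–George logit combination to gene level (within
  patient, then across patients) with Benjamini–Hochberg FDR.
- **Cell-type enrichment.** "Altered transcripts" (gene of a concordant
  event's promoter, gene and affected TF both expressed in the cell
  type), stratified by MAF (0–2%, 2–4%, 4–10%), with Fisher tests of
  altered-vs-expressed proportions between cohorts per cell type
  (test 1: promoter events; test 2: enhancer events, concordant and
  discordant separately), plus network degree summaries.
- **Synthetic cohorts.** A deterministic generator that plants concordant
  GoI/LoI events, allelic imbalance and a cell-type burden with full
  truth tables, so every stage is validated end to end without
  controlled-access patient data.

## Worked example

```r
library(rewirekit)

sim <- simulate_cohort(sim_config(seed = 42))   # 8 + 8 patients, 2000 variants
qc  <- filter_interactions(sim$interactions)
events <- enumerate_events(sim$variants, qc$kept, sim$regions, sim$cohort)
table(events$direction, events$concordance)
#>       concordant discordant
#>   GoI         50       2107
#>   LoI         20          0

e1 <- enrichment_test1(events, sim$expression$mean, sim$tf_map)
head(e1[order(e1$q), c("cell_type", "stratum", "altered_case",
                       "altered_control", "odds_ratio", "q")], 1)
#>   cell_type stratum altered_case altered_control odds_ratio           q
#> 1       CT1    MAFa           35               0        Inf 1.39732e-10

evaluate_recovery(sim, events, enrichment = e1)[c("event_sensitivity",
                                                  "event_specificity",
                                                  "burden_top")]
#> $event_sensitivity [1] 1
#> $event_specificity [1] 1
#> $burden_top        [1] TRUE

fisher_two_tailed(851, 7839, 230, 3853)
#> $odds_ratio [1] 1.818612
#> $p          [1] 4.803847e-16
```

The 50 planted concordant gain-of-interaction and 20 loss-of-interaction
events are recovered exactly; all background events (variants on
interactions present in every patient) are correctly discordant. The
planted cell-type burden surfaces as the minimum q in enrichment test 1,
and the last call shows the tier-gene enrichment statistic computed from a
published 2×2 event-count table.

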
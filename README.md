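# paralobind

Analysis pipeline for comparing the promoter-binding preferences of
paralogous transcription factors (TFs) profiled by ChEC-seq — the
MNase-fusion assay in which the two end positions of each sequenced
fragment mark the enzyme's cut sites next to wherever the TF binds.

Whole-genome duplication left yeasts with many retained TF pairs. Given
cut-site coverage for both paralogs, for each paralog in the other's
deletion background, and for a non-duplicated ortholog (a proxy for the
ancestral TF), the package quantifies how the two copies diverged:
whether they split the ancestral targets (sub-functionalization), one
acquired new targets (neo-functionalization), or they remained
interchangeable — and whether the protein sequences diverged with the
same asymmetry.

## What it computes

* **Coverage**: per-base cut-site tracks from BED/BedGraph, normalized
  to genome-wide mean 1; repeat QC (>200,000 fragments or pbs
  correlation r > 0.9); mean strain profiles; a "no reliable profile"
  flag for strains whose repeats agree only at chance level.
* **Promoter binding**: promoters from the start codon to 700 bp
  upstream of the TSS (truncated at verified ORFs); the
  promoter-binding signal `pbs(g) = Σ coverage` over promoter `g`;
  z-scores; targets at `z > min(q99(z), 3.5)`; regulatory circuits of a
  pair (the 4 auto-/cross-binding edges, classified up to paralog
  exchange into 9 non-empty classes).
* **Divergence**: repeat-aware strain correlations (mean ± sd over all
  `nA x nB` repeat pairs); robust-regression slope adjustment of
  deletion/swap profiles with gene changes
  `log2((pbs_adj + 700)/(pbs_wt + 700))`; divergence asymmetry
  `|corr(P1, orth) − corr(P2, orth)|`; "new"-target percentages
  (paralog `z > 4.5` vs ortholog `z > 3.5`); fate labels
  (conserved / sub / neo / biased); robustness–fragility of a TF to its
  paralog's deletion.
* **Sequence preference**: scores for the 8192 canonical 7-mers from a
  footprint-aware filter (21 nt minus 7 nt moving average, negatives
  zeroed) over promoter positions; PWM simplification to the 5 most
  informative positions; exact-match promoter scanning; mean signal
  around motif occurrences.
* **Protein evolution**: BLOSUM62 global-alignment conservation
  profiles (20-residue moving average); DBD residue classes
  (conserved > 50% of max; specificity-conferring > 150% of mean SR)
  and substitution statistics over four biophysical classes;
  calibrated tree-distance asymmetry (all distances scaled so the mean
  calibration-leaf-to-ancestor distance is 1).
* **Synthetic data**: genomes with planted motifs, cut-site tracks with
  protected footprints and flanking cut bands, paralog scenarios with
  controllable sharing/asymmetry/new targets and deletion responses,
  and protein families evolved on known trees — the ground truth behind
  every test.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
simulated reference scenario (300 genes, 15 ancestral targets, half
shared, asymmetry 0.5 toward P1, 25% new targets for P2, 500k fragments
per repeat) and write tables under `results/`. Condensed, the pipeline
is:

```r
library(paralobind)

spec <- scenario_spec(seed = 42, shared_target_fraction = 0.5,
                      asymmetry = 0.5, new_target_fraction_P2 = 0.25)
sc <- make_paralog_scenario(spec,
        deletion_response = c(P1 = "competitive_release",
                              P2 = "independent"))
promoters <- define_promoters(sc$annotation)

reps <- lapply(sc$tracks, function(tr)
  lapply(tr, function(t) pbs(normalize_coverage(t), promoters)$pbs))
profiles <- lapply(names(sc$tracks), function(s)
  zscore_and_maxnorm(pbs(mean_profile(
    qc_repeats(repeat_set(sc$tracks[[s]]), promoters)), promoters, s)))
names(profiles) <- names(sc$tracks)

classify_fate(reps$P1, reps$P2, reps$orth,
              p1_profile = profiles$P1, p2_profile = profiles$P2,
              orth_profile = profiles$orth,
              p1_in_del = reps$P1_d2, p2_in_del = reps$P2_d1)
```

prints

```
fate_summary: biased_neo_sub
  corr(P1,P2) = 0.526; corr with ortholog: P1 0.962, P2 0.636 (asymmetry 0.326)
  conserved paralog: P1; % new targets: P1 0.0, P2 16.7
```

Read: the pair has diverged (r = 0.53 < 0.8); P1 still binds nearly the
ancestral repertoire (r = 0.96 with the ortholog) while P2 has moved
away, partly toward genuinely new targets (17%) — an asymmetric mixture
of sub- and neo-functionalization, which matches the planted scenario
(asymmetric retention plus some new P2 targets). The deletion analysis
(`analysis/04`) then reports

```
P1 vs P2 correlation: 0.526 before, 0.682 after p2 deletion -> robust
robust slope 0.831; 6 genes change significantly (6 of 6 released targets among them)
```

— P1 expands onto P2's vacated targets (competitive release), and the
slope-adjusted change analysis flags exactly the six released targets.
On the sequence side (`analysis/05`), the planted motif `TGACTCA` ranks
4th of 8192 canonical 7-mers in the P1 preference table, and 99.8% of
target-promoter signal lies within 50 bp of a motif occurrence.

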
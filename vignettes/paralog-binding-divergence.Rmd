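---
title: "Quantifying binding-preference divergence of duplicated transcription factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying binding-preference divergence of duplicated transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralobind)
```

## The problem

Whole-genome duplication (WGD) left budding yeasts with many pairs of
paralogous transcription factors (TFs). After duplication the two copies
can keep binding the ancestral promoter targets, split them between each
other (sub-functionalization), or one copy can acquire new targets while
the other keeps the ancestral role (neo-functionalization). ChEC-seq
profiles where each TF binds: the TF is fused to MNase, which cuts DNA
next to wherever the TF sits, and the two end positions of every
sequenced fragment mark those cut sites at base resolution.

`paralobind` implements the quantitative layer of such a study: from
per-base cut-site coverage to promoter-binding signals and target calls,
to divergence statistics of a paralog pair against a non-duplicated
ortholog (the proxy for the ancestral TF), to sequence-level binding
preferences (canonical 7-mers, simplified motifs) and protein-evolution
asymmetry on a phylogeny. A synthetic-data generator with known ground
truth drives all tests, so each stage is validated end to end without
any external data.

## Coverage and promoter-binding signal

Raw tracks count fragment ends per base. Each track is normalized so the
genome-wide mean coverage is one; all downstream quantities live on this
scale. Repeats pass quality control when they have more than 200,000
fragments or correlate above r = 0.9 with the other repeats; at least
two passing repeats are averaged into a strain profile. Reproducibility
is judged at the promoter level (see below) rather than per base,
because per-base correlations are dominated by sequencing depth. A
strain whose repeats correlate only at chance level (mean internal
r < 0.2 across four or more repeats) is flagged as carrying no reliable
profile — the behaviour of a TF that binds DNA only together with its
now-deleted paralog — and is excluded from comparisons rather than
interpreted.

The promoter of a gene runs from its start codon to 700 bp upstream of
the TSS (or of the start codon when no TSS is known), truncated at the
nearest verified ORF; promoters of divergent gene pairs may share
intergenic bases. The promoter-binding signal (pbs) is the sum of
normalized coverage over the promoter, so a featureless track yields
pbs = length. Per TF, pbs values are z-scored over all promoters
(population sd; a convention choice, configurable) and significant
targets are promoters with z above the 99% quantile capped at 3.5. The
cap matters: a strongly bound TF pushes its real targets far into the
tail, and without the cap the quantile would call only the top 1%.

Two z-score subtleties are worth knowing. First, z magnitudes depend on
the fraction of bound promoters: a TF binding fraction $f$ of all
promoters concentrates its signal there, so target z-scores sit near
$\sqrt{(1-f)/f}$ — about 10 when 1% of promoters are bound, but only
about 4.4 at 5%. Thresholds of 3.5–4.5 therefore assume realistically
sparse target sets. Second, the 99% quantile is taken over z-scores (the
z and raw-pbs quantiles coincide up to the affine map, so only the cap
interacts with the choice).

## Comparing strains and classifying fates

Similarity between strains A and B is the mean Pearson correlation over
all `nA x nB` repeat pairs of pbs vectors, with its sd as the error bar;
correlations are computed on linear pbs (no transform; configurable).
When a strain is compared with itself the same-repeat pairs are
excluded.

Deleting a paralog redistributes relative signal (coverage is
mean-normalized), so gene-specific changes are measured after a robust
linear regression (iteratively reweighted least squares with bisquare
weights, tuning constant 4.685 — the classic `robustfit` default) of
mutant on wild-type pbs across the 50 strongest-bound wild-type
promoters (plus any others with z > 3.5). Only the slope is used:
`pbs_adjusted = pbs_mutant / slope`, and the change is
`log2((pbs_adjusted + 700) / (pbs_wt + 700))`. The pseudocount 700 is
the expected pbs of an average promoter under a featureless track, so
unbound promoters sit at a log-ratio of zero instead of amplifying
noise. Genes change significantly when their absolute log2 change
exceeds the mean of the top-50 changes by one sd; the absolute value is
used because the direction of a real change is informative but its
significance should not depend on it (the underlying convention is
ambiguous either way, so it is documented here and kept configurable in
spirit — negating all changes leaves the significant set unchanged).

Fate classification compares each paralog with the ortholog:
`divergence_asymmetry = |corr(P1, orth) - corr(P2, orth)|`, measured in
the other paralog's deletion background when available (removing
competition isolates intrinsic preference). "New" targets of a paralog
are its strong targets (z > 4.5) not among the ortholog's targets
(z > 3.5); the asymmetric thresholds make the ortholog set deliberately
permissive so that borderline ancestral targets are not miscounted as
new. A pair with corr(P1, P2) >= 0.8 is conserved; otherwise high
asymmetry (>= 0.4) with a mostly-new less-conserved paralog (>= 50% new)
is neo-functionalization, low asymmetry (<= 0.1) with few new targets on
both sides (<= 25%) is sub-functionalization, and everything between is
a biased mixture. The 0.8 divergence cut-off is the primary,
literature-anchored threshold; the remaining four are package defaults
(all arguments of `classify_fate()`), chosen to separate the pure
scenarios cleanly, and deliberately conservative: mixtures fall into
`biased_neo_sub` rather than being forced into a pure class.

Robustness versus fragility of a TF to losing its paralog is the change
in its correlation with the paralog's wild-type profile: an increase
after deletion (it now reaches the paralog's targets) is robustness by
compensatory access; a decrease (it loses shared targets, as an obligate
heterodimer would) is fragility.

The four auto-/cross-binding edges of a pair (each TF on its own and on
its paralog's promoter) define its regulatory circuit. Identifying
circuits up to exchanging the paralogs collapses the 16 edge subsets to
10 classes, 9 of them non-empty — `enumerate_circuit_classes()` verifies
this by exhaustion.

## Sequence preferences: 7-mers and simplified motifs

Every genomic position is indexed by the 7-mer around it (−3..+3), with
a word and its reverse complement sharing one canonical index — 8192
classes in total. Because a bound TF protects its site while MNase cuts
right next to it, the cut-site signal is filtered with the difference of
a 21 nt and a 7 nt centered moving average: cuts 4–10 bp from a position
raise its score, cuts within ±3 bp lower it, and negative responses are
set to zero. Promoter positions (ORFs excluded) contribute their
filtered signal to their canonical index; a 7-mer's score is the mean
over its contributing positions (position-level pooling, so frequent
words are not inflated). Moving-average windows must lie fully inside
the contig; positions within 10 bp of an edge are skipped.

In vitro PWMs are reduced to scannable patterns: per column the
information content is $2 + \sum_b p_b \log_2 p_b$, the five
highest-content columns keep their most probable base, and all others
become `N`. Promoters are scanned for exact matches on both strands
(greedy left-to-right non-overlapping per strand, the usual
regular-expression semantics; an overlapping mode is available);
palindromic double-strand matches at the same position are deduplicated.
When several PWMs exist per TF, the cross pair with the smallest
correlation distance (after ungapped sliding alignment) represents the
pair. Signal around occurrences is summarized as the mean over
orientation-aligned windows (`meta_signal()`) and as the percentage of
promoter signal within 50 bp of an occurrence, with overlapping windows
counted once.

## Protein evolution

Conservation along a protein is profiled by globally aligning two
sequences under BLOSUM62 (affine gaps, open 11 / extend 1 — the standard
pairing; only the matrix is anchored in the source method, the gap costs
are package defaults), mapping each reference residue's substitution
score back onto the ungapped sequence (residues aligned to a gap get the
matrix minimum, −4) and smoothing with a 20-residue centered moving
average, truncated at the ends rather than padded.

Within aligned DNA-binding domains, residues with conservation scores
above 50% of the maximum are family-conserved and residues with
similarity-regression (SR) scores above 150% of the domain mean are
specificity-conferring; where both rules fire, specificity takes
precedence so the classes partition the positions. Substitutions are
graded by four biophysical classes — positive (K, R, H), negative
(D, E), hydrophilic (T, S, N, Q, C, Y), hydrophobic (A, W, V, I, L, P,
F, M); glycine belongs to none and always grades as dissimilar, and gap
positions count as (dissimilar) substitutions.

Tree-distance asymmetry consumes a phylogeny with branch lengths (tree
inference itself is out of scope). To remove family-specific rate
differences, all distances are divided by the mean path length from two
calibration leaves — two species that diverged before the duplication —
to their common ancestor, which is thereby set to one. The calibrated
distances from the paralogs' own common ancestor to each paralog leaf
give `delta_D`, with the shorter distance identifying the conserved
copy.

## The synthetic-data generator

`scenario_spec()` fixes the study conditions; the defaults are the
conditions under which the pipeline is validated:

* 300 genes at fixed 1500 bp spacing on alternating strands (genome
  450 kb); TSS 20–200 bp upstream of the ATG, uniform; one motif
  instance (`TGACTCA` by default) planted per promoter 250–450 bp
  upstream of the start codon, with chance promoter matches scrubbed so
  planted occurrences are exactly the promoter occurrences.
* An ancestral target set of 15 genes (5% of promoters). This is larger
  as a fraction than a typical specific TF in a real genome (~1%), a
  deliberate desk-scale compromise: it keeps target z-scores (~4.4)
  above the calling thresholds while the whole genome stays small
  enough to simulate hundreds of times in tests.
* 500,000 fragments per repeat, two repeats per strain. Each bound-site
  fragment contributes two cut positions drawn uniformly from 20 bp
  bands flanking a fully protected ±3 bp footprint on the motif center:
  the footprint is the motif core the TF sits on, and cuts start
  immediately beside it, which is the geometry the 7/21 nt k-mer filter
  is designed to detect. The cut-position distribution within the bands
  is not constrained by any published measurement; uniform is the
  simplest shape consistent with "cutting nearby, protection on site".
* Background cutting is homogeneous at 0.2 cuts/bp (promoters and ORFs
  alike), charged against the same read budget so every track carries
  exactly `2 x reads_per_repeat` cut events.
* Target affinities are log-normal (sdlog 0.25) and inherited by the
  descendant TFs from the ancestor, so paralog–ortholog correlations
  reflect target-set overlap rather than affinity re-draws.
* One global seed drives label-hashed sub-streams per TF and repeat, so
  adding a strain or repeat never perturbs the draws of earlier ones,
  and identical specs give byte-identical outputs.

`make_paralog_scenario()` splits the ancestral set: a `shared` fraction
stays common to both paralogs, the remainder goes to P1 with weight
`0.5 + asymmetry/2`, and P2 gains `new_target_fraction_P2 x 15` novel
targets. Deletion backgrounds model four responses: unchanged targets,
competitive release (the survivor gains the deleted copy's exclusive
targets at half affinity), obligate-dimer collapse (it loses the shared
targets), or complete loss of specificity (pure background — matching
the "no reliable profile" flag upstream).

Protein families are evolved with `phangorn`'s JTT sampler along a
rate-scaled tree, with the DBD segment at one fifth of the global rate;
the scaled tree is the ground truth for distance recovery.

What the generator does **not** emulate: nucleosomes and chromatin
accessibility, MNase sequence bias, PCR duplicates, mappability, diffuse
or cooperative binding, and condition-dependent binding. Passing tests
therefore demonstrate that the statistics recover planted structure
under idealized noise, not that they overcome every artifact of real
ChEC-seq data.

## Validation scale and numerical choices

The multi-seed recovery study (`recovery_study()`) runs the full
pipeline over 20 seeds at full depth under the default conditions with
asymmetry 0.3 — the weakest asymmetry the fate analysis is expected to
resolve — and checks that repeats correlate above 0.9, that the
conserved paralog is identified in at least 95% of runs, that a planted
proportionality slope of 0.5 (with one zeroed-out target) is recovered
to machine precision with the lost target flagged, and that the
estimated shared-target fraction tracks the planted one within 0.1.

Fate *labels* (pure neo vs pure sub) are validated on a larger universe:
2000 promoters with 60 ancestral targets (3%). This is a statistical
necessity, not a tuning knob: correlation asymmetry under an even split
has sampling noise of roughly $1/\sqrt{n_\mathrm{targets}}$ from the
affinity draws, so with only ~7 targets per paralog the noise equals the
0.1 sub/neo boundary, while with ~30 it falls well below. A real yeast
genome (~5400 promoters, dozens of strong targets per specific TF) is
precisely the regime in which these thresholds are meaningful, and the
larger scenario reproduces it at tractable cost.

Other numerical conventions, in one place: coordinates are 0-based
half-open everywhere internally (BED-native); ties in top-n selections
break lexicographically by gene id; the pair top-40 selection scores
promoters by the larger of the two z-scores (max rule; `sum` available)
— the underlying selection rule is not pinned down by the source
analysis, so it is a documented, configurable choice; moving-average
windows truncate at edges (proteins) or skip edge positions (genomic
k-mers); z-scores use the population sd; the robust fit includes an
intercept but only the slope is used; degenerate inputs (all-zero
tracks, constant pbs vectors, empty target sets, zero calibration
distances) raise informative errors rather than propagating NaN.

## Known limitations

* The fate thresholds beyond the 0.8 conservation cut-off are
  package-defined defaults; real pairs near a boundary should be read as
  a continuum (asymmetry plus new-target fractions), not as hard calls.
* The 7-mer table is built from a single strain profile at a time;
  comparisons across strains assume equal sequencing depth after
  normalization.
* `global_align()` delegates to `Biostrings::pairwiseAlignment`; for
  sequences with long terminal gaps a local or overlap alignment may be
  more appropriate than the global mode used here.
* Tree metrics require the calibration species' divergence to predate
  the duplication; the function does not verify this topologically
  beyond using the leaves it is given.
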
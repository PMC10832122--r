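---
title: "TRpredict: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TRpredict: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

TRpredict classifies tandem-repeat (TR) loci as pathogenic or benign *if
expanded*, from the genomic context of the locus rather than from allele
frequencies. This vignette is the package's own account of the science: the
models and their assumptions, the parameters that matter, the numerical
choices, what the synthetic generators do and do not emulate, and the
design decisions taken where the design was genuinely open.

## The classification model

Each locus is represented by a fixed, ordered numeric feature vector
(`annotateTRs()`):

* **Binary annotation overlaps.** One 0/1 flag per configured track (TAD
  boundaries, open regulatory regions, transcription-factor binding sites,
  expression-TR status, ...). A locus overlaps a track if they share at
  least one base under half-open BED semantics; a boundary touch is not an
  overlap. Tracks are plain BED files; no track is special-cased.
* **Genic context.** Region one-hot (exon / intron / intergenic), exon
  position one-hot (first / middle / last / none, in transcription order),
  and independent 5'UTR / 3'UTR / promoter flags. Promoters are an input
  track, not computed from transcription starts. A locus overlapping
  several genes is keyed to the gene with the largest overlap, ties broken
  by lexicographically smallest symbol, purely for determinism.
* **Quantitative scores.** Gene-keyed constraint (pLI, LOEUF) and
  positional conservation (GERP, averaged over overlapping track
  intervals), with neutral imputation when missing: pLI 0, GERP 0, LOEUF
  2.0 — each the least-constrained end of its natural scale, and
  configurable. Distance to the nearest gene span (0 when genic) keeps
  intergenic loci informative.
* **Motif features.** Per-base percentages and GC content of the repeat
  unit. A degenerate `N` (as in the polyalanine motif GCN) counts toward
  motif length but toward no base, so percentages stay well-defined without
  inventing base identities. Optional hallmark flags: known disease motif
  (equality up to cyclic rotation and reverse complement), pure-GC motif,
  polyglutamine (rotation in CAA/CAG) and polyalanine (rotation in
  GCA/GCC/GCG/GCT) trinucleotides.
* **Star-network topological indices.** The motif repeated ten times is
  embedded as a star-shaped tree: one central node, one node per sequence
  position, positions sharing a symbol forming a path ("ray") off the
  center in sequence order. On this unweighted graph we compute Shannon
  entropy of the degree distribution, spectral moments (traces of adjacency
  powers, orders 1–5 by default), Wiener and Harary distance sums, Gutman
  and Schultz degree–distance indices, the Balaban J index, Kier–Hall chi
  connectivity of orders 0–2, and the Randic index. The originating tool's
  exact embedding (node weights, Markov normalization) is not restated
  anywhere we could implement from, so the construction above is our
  concrete, fully specified reading: order-preserving, unweighted,
  distances by BFS. Degree-distribution entropy was chosen as a standard
  graph entropy computable without the tool's internal matrices. These
  indices are invariant under node relabeling and depend only on the
  symbol sequence, which the tests assert.
* **Tissue category.** The host gene's maximum-expression tissue is mapped
  to nervous / other / unknown. The nervous-system set is a configurable
  list of name patterns (default: Brain, Nerve, Spinal cord, Pituitary),
  since no canonical enumeration exists. Intergenic loci are `unknown`.

The column set and order are fully determined by the configuration; a
prediction matrix whose columns differ from the training schema is a hard
error rather than a silent misalignment.

**The ensemble.** Two members: an RBF/linear SVM with Platt-calibrated
probabilities, fit on standardized features, and a gradient-boosted tree
model (logistic objective) on raw features. Standardization uses the
population (divide-by-n) standard deviation, is fitted on training rows
only, and passes constant columns through centered. The decision rule is
*pathogenic iff either member's probability strictly exceeds 0.5*; the
confidence score is the sum of the two probabilities (0–2). The either-or
rule trades precision for recall by construction: the two members rely on
different feature families (the SVM on constraint scores and motif
composition, the tree model on topological indices), so their union
recovers loci either alone would miss. The strict inequality makes the
boundary pair (0.5, 0.5) benign.

**Evaluation.** Leave-one-out cross-validation refits the scaler and both
members inside every fold, so the held-out locus never leaks into scaling
or fitting. Metrics: accuracy (percent), precision, recall, F1 from
confusion counts (zero denominators yield an explicit undefined flag, not
a silent zero); AUROC by trapezoid over the tie-grouped ROC; AUPRC by
step-wise (right-continuous precision) summation, which avoids the
optimistic bias of trapezoidal interpolation on PR curves.

**Hyperparameters.** Defaults: SVM C = 1, gamma = "scale"
(1/(p·Var(X))), RBF kernel; 100 boosting rounds of depth 3. Grid search
(`gridSearchEnsemble()`) scans C in {0.1, 1, 10, 100}, gamma in
{0.01, 0.1, 1, "scale"}, kernel in {radial, linear}, rounds in
{50, 100, 200, 400}, depth in {2, 3, 4, 6}, scored by 5-fold
cross-validated F1 with ties broken by first-in-grid order. F1 was chosen
as the selection metric because the training design is heavily imbalanced
and accuracy would reward the trivial classifier. Feature selection offers
permutation importance (mean AUROC drop over column permutations) and
correlation pruning: groups closed transitively over |Pearson r| > 0.9
keep the member whose retention scores the highest AUROC.

## Interval enrichment

`intervalFisher()` asks whether two interval sets co-occur more than
chance. Both tracks are merged (union) first so nested input intervals are
not double-counted. The 2x2 table is: A-intervals hitting B, A-intervals
missing B, B-intervals missing A, and an estimated count of empty "slots"
in the rest of the genome: `round(genome_size / slot) − (other cells)`,
where the slot is the *sum* of the two tracks' mean merged-interval widths.
The sum is deliberate: two randomly placed intervals collide when their
starts fall within the sum of their widths, and with this window the odds
ratio of independently placed tracks is centered at 1 (a simulation the
test suite runs); using a single mean width inflates it about two-fold.
This slot model is an explicit approximation — it ignores chromosome ends,
gaps and width heterogeneity — and bit-parity with any external
interval-statistics tool is a non-goal.

The test itself is the two-sided Fisher exact test; the odds ratio is the
conditional maximum-likelihood estimate under the noncentral
hypergeometric model and the 95% CI inverts the one-sided exact tests
(2.5% each side), zero cells giving 0 or infinite bounds. The suite checks
p-values and estimates against a brute-force enumeration / likelihood-scan
oracle over all tables with small totals (estimates to 1% — the library's
root-finding precision, not a model difference). Enrichment of one set
*relative to another* uses the CI-separation rule: A is significantly more
enriched than B iff A's lower bound exceeds B's upper bound.

## The outlier pipeline

For a case against a control cohort of depth-normalized anchored
in-repeat-read counts, three per-locus statistics: the z-score against the
control mean and (sample) standard deviation, with ±Inf sentinels when
controls are constant; the Gaussian-KDE tail probability
`mean(pnorm((case − x_i)/h, lower.tail = FALSE))` with Silverman's
rule-of-thumb bandwidth floored at 1e-6 (falling back to the empirical
fraction when controls have fewer than two distinct values); and the
strict empirical fraction of controls above the case. z is monotone
increasing and shift/scale-equivariant; both tail statistics are monotone
non-increasing in the case count — all asserted as properties.

Candidates must pass every clause: case count ≥ 5, control expansion
frequency < 1%, non-intergenic, reference-repeat origin, not Alu-derived,
not blacklisted. Thresholds are exposed because no canonical downstream
cutoffs for z/KDE/percent exist; the default report simply sorts
candidates by descending z. The Alu clause is resolved as *keep
reference-locus TRs, drop Alu-only TRs*, both provenance flags being
inputs; the blacklist is an input BED (the package ships only synthetic
stand-ins, never a real site list). Every record carries its rejection
reasons, making the cascade auditable and idempotent.

## Synthetic data: what it emulates, what it does not

`simulateTRDataset()` builds a 10-Mb single-chromosome toy genome with
evenly spaced three-exon genes (UTRs at the ends, 1-kb promoters), places
class-labeled loci by class-specific region probabilities, draws motifs
from a pathogenic pool (CAG/CGG/GCN/TTTCA/GGGGCC and kin) or uniform
random units, overlays each annotation track by per-class Bernoulli
overlap (plus locus-independent background intervals), and biases host
genes' top tissue toward the nervous system for pathogenic loci.
Defaults are fixed once: 40 pathogenic vs 745 benign loci (the training
design's class sizes); pathogenic region mix 0.50/0.40/0.10
exon/intron/intergenic vs benign 0.03/0.47/0.50; nervous-tissue
probability 0.37 vs 0.29 (echoing the reported genic-TR tissue
fractions); track contrasts of a few-fold, milder than the published
odds ratios so that recovery is a real test. `simulateIRRMatrix()` draws
control counts from Poisson(λ = 1) over 500 controls and spikes one case
at count 20; background loci are given control expansion frequencies of
1–10% — they model *common polymorphic* repeats, which is exactly the
premise of the frequency filter, and it makes "no spikes, no candidates"
hold by construction.

What passing tests on these fixtures show: the statistical machinery
recovers planted signal at realistic effect sizes and returns chance-level
results under null configurations. What they do not show: performance on
real genomes — real annotation tracks are correlated, real benign repeats
are not uniform in motif space, real IRR counts are overdispersed and
depth-correlated, and the published headline numbers depend on thirty
external annotation sources and control cohorts that desk-scale fixtures
cannot reproduce. The catalog of 61 known pathogenic loci is shipped
verbatim (no coordinates are fabricated for it) and is used to check the
decision rule and the onset correlation, not to claim real-data accuracy.

## Numerical choices and degenerate inputs

* Coordinates: 0-based half-open in every file, 1-based closed GRanges in
  memory, converted only at the I/O boundary.
* LOOCV under the null: a single label-shuffled LOOCV AUROC at n = 60 has
  a spread of roughly ±0.1 *plus* the well-known pessimistic
  (anti-learning) bias, so chance-level checks are asserted on means over
  several shuffles or generator seeds, never on a single run.
* Determinism: boosting is single-threaded with a fixed seed; the SVM's
  Platt calibration is seeded; identical calls are bit-reproducible, which
  the suite asserts.
* Degenerate cases with defined answers return them (constant scaler
  columns pass through centered; constant controls give ±Inf z); cases
  without one raise errors naming the offending file and line (malformed
  BED) or the violated precondition (degenerate 2x2 margins, single-class
  labels, schema mismatches).
* Problem sizes in the test suite (LOOCV at n = 24–120, enrichment at
  500 + 500 loci, enumeration over all tables with totals ≤ 16 plus a
  sample up to 40) were chosen so the full suite exercises every property
  at comfortable desk scale.

## Known limitations

The star-network embedding is one concrete reading of a loosely specified
construction; a weighted or Markov-normalized variant would change the
index values (not their invariances). The slot-count null of the interval
Fisher test is approximate by design. The ensemble ships exactly two
members; the five additional baseline model families often compared in
this setting are out of scope. Nothing in the package lifts coordinates
between genome builds, and the packaged catalog carries no coordinates at
all.
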
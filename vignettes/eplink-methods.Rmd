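---
title: "Predicting enhancer-promoter interactions from regulatory signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting enhancer-promoter interactions from regulatory signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Enhancers regulate genes over large genomic distances, and which enhancer
talks to which promoter is cell-type specific. Chromosome-conformation
assays (5C, Hi-C, ChIA-PET) measure such contacts directly but are
expensive and incomplete. `eplink` treats the problem as supervised
classification: given one-dimensional regulatory genomics signals
(ChIP-seq peak calls for histone marks and transcription factors, DNase I
hypersensitivity, RNA-seq expression), predict whether a candidate
(enhancer, promoter) pair interacts in a given cell line.

## Region definitions and features

Coordinates are 0-based half-open (BED convention) internally; 1-based TSS
tables are converted at parse time. A region is a *promoter* if a TSS lies
inside it or strictly closer than 2500 bp; otherwise it is *distal* (a
candidate enhancer). Each region is summarized against a panel of peak
tracks: in BINARY mode a data set contributes 1 when any peak overlaps the
region by at least one base; in CONTINUOUS mode it contributes the largest
-log10(P) enrichment among overlapping peaks. A pair is encoded by
CONCAT (the two n-vectors side by side, suffixes `_E`/`_P`) or PRODUCT
(elementwise product; for continuous signals a 0.01 correction is added to
each region value *before* multiplying, so a pair is not zeroed when only
one side carries signal). Two optional extras follow: the Pearson
correlation of the two region vectors (defined as 0 when either vector has
zero variance — such pairs carry no co-variation signal and a hard NA would
poison the design matrix) and the promoter gene's RPKM. The default
encoding is binary CONCAT with correlation and expression (2n + 2
features), the configuration that performed best in the work this package
follows; a promoter region overlapping several genes carries all their ids
and uses the maximum RPKM, preserving "active promoter" semantics.

## Training sets

Positives come from measured interactions: each interaction must map one
anchor onto a distal region and the other onto a promoter region
(>= 1 bp overlap, either orientation); pairs farther apart than 1 Mb are
dropped. Because contact frequency decays with distance, negatives are
*distance-matched*: pairs are binned into 10 kb gap bins and, for each
positive, `ratio` negatives (1 by default, 10 for the harder evaluation
setting) are drawn uniformly without replacement from the same bin. When a
bin runs out, the draw expands symmetrically to adjacent bins and the event
is logged — the per-bin negative histogram equals `ratio` times the
positive histogram up to exactly those logged events. "Distance" is the gap
between closest edges (0 when regions overlap): unambiguous for
unequal-length regions. For loop calls on a binned genome
(`build_hic_examples`), the genome is tiled at 5 kb, bins are classified by
the same TSS rule, a positive is any (promoter bin, distal bin) pair
spanning a loop at any input resolution, and negative sampling additionally
matches on non-zero promoter expression, since the negative space is
otherwise dominated by silent promoters.

## Classifiers and evaluation

The primary model is a Random Forest with 500 trees (other hyperparameters
are the standard defaults: sqrt(d) features per split, unlimited depth).
L1-regularized linear regression (labels recoded to -1/+1, output min-max
mapped to [0, 1]) and L1-regularized logistic regression are baselines;
their penalty is chosen within each cross-validation fold by an inner
5-fold search over 50 log-spaced values from the all-zero-model lambda
down by four decades. Performance is the area under the precision-recall
curve with the nonlinear interpolation of Davis and Goadrich: between
consecutive achievable PR points, intermediate points are created at unit
true-positive increments with false positives interpolated linearly, and
the area is the trapezoidal sum; tied scores collapse into a single
threshold step so arbitrary within-tie orderings cannot inflate the area.
Cross-validation is stratified by label (10 folds). The chance baseline is
obtained by shuffling predicted probabilities among pairs; its mean sits
at (slightly above, in small samples) the positive fraction.

## Minimal data-set panel

Feature selection is hybrid, because the two ingredients fail differently:
Random Forests classify well but select nothing; sparse linear models
select but classify worse. Arm one is a multi-task Group Lasso across the
per-cell-line classification tasks: coefficients form an N x K matrix B
whose rows (one per feature, across all cell lines) are penalized by the
L1/L2 norm `sum_j ||B_j||_2`, zeroing entire rows so a feature is kept
only if useful in *all* tasks. The unsquared row norm is used: a squared
variant is a ridge penalty that cannot zero rows, contradicting the very
point of the construction (a `squared_penalty` flag exposes it for
comparison). The solver is a monotone proximal-gradient loop — gradient
step on the squared or logistic data loss, then the block soft-threshold
`B_j <- B_j max(0, 1 - t*lambda/||B_j||_2)` — with a Lipschitz step size
and backtracking; for `lambda >= lambda_max` (the largest gradient row
norm at B = 0) it returns the exact zero solution. Columns are centered
and unit-scaled per task first so binary peak indicators and RPKM share a
penalty scale. Features nonzero in at least 8 of 10 cross-validation folds
are ranked by summed absolute weights; the top 20 survive. Arm two takes
each cell line's Random Forest out-of-bag permutation importance and keeps
features in the top 20 of at least two cell lines, collapsing `_E`/`_P`
sides to data sets (a data set qualifies if either side does). The
intersection of the two arms seeds a correlation-guided refinement:
data sets are grouped into blocks by |r| > 0.7 (uncorrelated data sets
form singleton blocks, so every panel member is examined — this is the
package's committed reading of a search procedure whose full order the
source material leaves open); within each block, removals of up to three
members (largest removals tried first, favouring parsimony) are accepted
when the mean cross-validated AUPR over all cell lines drops by at most
0.01; one final pass re-adds excluded candidates only if they improve the
mean AUPR by more than that tolerance. On the synthetic fixture this
recovers the planted panel exactly, with one representative per fully
collinear block (which representative survives is arbitrary among
identical columns).

## Predicting in a new cell line

Three combiners pool the per-cell-line classifiers for a target cell line
with no training data. *Percentile*: convert each classifier's
probabilities to percentile ranks (average ranks for ties, divided by N so
the maximum is 1) and average — invariant to monotone miscalibration of
any classifier. *Spectral Meta Learner*: weight classifiers by the leading
eigenvector of the K x K covariance of their probability columns and score
each pair by the dot product; eigenvectors are sign-ambiguous, so the
orientation with non-negative entry sum is fixed (positive weights
correspond to better-than-chance classifiers in the SML derivation). The
covariance is computed on probabilities rather than on binarized votes
(the original SML formulation uses votes; probabilities retain the full
ranking information and avoid an arbitrary vote threshold). *SimpleMerge*: concatenate all
source training sets and train one forest. Genome-wide maps score every
same-chromosome candidate pair closer than 1 Mb over universal region sets
(per-cell-line enhancer calls merged when overlapping or abutting, < 200 bp
discarded; promoters as TSS +/- 2500 bp), assign within-run percentile
ranks, and keep edges above the 0.9 percentile as the high-confidence
network. The within-run percentile transform is applied to every
combiner's scores so that "90th percentile" is well-defined regardless of
the combiner.

## Validation and network characterization

Predicted networks are validated two ways. Fold enrichment against an
independent interaction list maps experimental anchors onto the
prediction's region sets and computes `(n1/n2)/(m1/m2)` with `m2` the
candidate pair universe used for prediction — the denominator consistent
with how `n2` and `m1` are counted. Contact-count contrast maps each edge
to the 10 kb bin pair containing its anchor midpoints and compares top- and
bottom-percentile edges by a two-sample Kolmogorov-Smirnov test.
Cell-line-specific edges (above the 0.9 percentile in A, below 0.8 in B;
the 0.8-0.9 band in B is reported as ambiguous rather than forced into a
category) are split by the B-side status of their regions: an enhancer is
ON with any of DNase I, H3K27ac, H3K9ac; a promoter is ON with H3K4me3 or
DNase I but not H3K27me3. Agreement between two categorizations is the
per-category F-score. High-confidence networks are further characterized
by best-of-10-restart K-means (K = 5) on binary region signal vectors,
with cluster labels matched across cell lines by exact minimal-distance
assignment over all K! matchings (automating a manual pattern-matching
step that is otherwise irreproducible); enhancer-cluster x promoter-cluster
enrichment uses the upper-tail hypergeometric test and fold
`(p/n)/(m/T)`; connected components are classified SINGLE/MI/MO/MIMO by
their enhancer and promoter counts; and gene sets from components with at
least five genes can be tested by hypergeometric enrichment with
Benjamini-Hochberg correction against user-supplied GMT annotations.

## The synthetic-data generator

Real peak tracks and interaction lists require large downloads, so the
package ships a generator whose defaults define its reference study
conditions: 4 cell lines; a 20 Mb genome (two chromosomes, 12 + 8 Mb);
500 TSS and 2000 enhancer candidates placed uniformly with enhancers at
least 2500 bp from any TSS; a 22-track panel (8 histone marks, 13
transcription factors, DNase I) with a correlated architectural block
CTCF/RAD21/SMC3 (within-block co-occurrence 0.8); and expression coupled
to promoter marks (active promoters draw log-normal RPKM, silent ones are
mostly zero). The planted truth follows the field's understanding of
looping: a pair can interact when the enhancer carries CTCF and H3K27ac
and the promoter carries H3K4me3, thinned by an exponential distance decay
(scale 100 kb, so both short- and long-range edges exist under the 1 Mb
cap) with the acceptance coin shared across cell lines. Cell-line
specificity has two separate dials mirroring the two biological regimes:
per-cell-line signal dropout (0.15) silences regions (enhancer-OFF
specific interactions), and independent interaction dropout (0.1) removes
interactions between regions that stay active (both-ON specific
interactions). Observation noise adds false peaks (0.02) and drops true
ones (0.05). These sizes give roughly 600-700 positives per cell line
(about 1400 labeled examples at 1:1 matching) — large enough for stable
AUPRs, small enough that the full pipeline runs in minutes on one core.
Base presence rates (0.3-0.55 by data-set class) were chosen once as
realistic peak frequencies for regulatory regions.

What the generator does *not* emulate: nucleotide sequence, TAD and
compartment structure, replicate-level count noise, peak-width variation
correlated with signal strength, and the strong gene-density
heterogeneity of real chromosomes. Tests passing on this fixture show the
machinery is correct and the statistical procedures behave as designed;
they do not certify accuracy numbers on real ENCODE-scale data.

## Numerical choices and degenerate inputs

* Group Lasso: nonzero-row tolerance `||B_j||_2 > 1e-8`; convergence at
  relative objective change `1e-8` (tighter where closed-form agreement is
  asserted); backtracking halves the step until the majorization holds.
* AUPR: precision at recall 0 is the first segment's precision when no
  false positive precedes it, else the limiting value 0; vertical PR
  segments (ties, negative-only thresholds) update the running precision
  so the next trapezoid starts from the dropped value.
* K-means restarts draw initial centers from distinct data vectors;
  a degenerate restart (emptied cluster) is redrawn, preserving
  determinism under the seed. K must not exceed the number of distinct
  vectors.
* SML requires at least one non-constant probability column; an all-
  constant matrix is an error, not a silent uniform weighting.
* Matched sampling is without replacement across the whole negative set,
  so no example is duplicated; two runs with the same seed are identical.
* Promoter flanks are computed on the stored 1-based TSS position
  (`[position - flank, position + flank)`), clipped at 0; the 1 bp offset
  against a strict 0-based conversion is immaterial at 2.5 kb flanks.

## Known limitations

* The refinement search is greedy and block-local; it will not find a
  better panel that requires a coordinated swap across blocks.
* Percentile thresholds assume the scored run is large enough for ranks
  to be meaningful; tiny candidate sets make "0.9 percentile" coarse.
* `simple_merge` assumes identical feature panels across cell lines and
  does not reweight for unequal training-set sizes.
* The generator's expression model is binary-activity driven; it does not
  produce the long-tailed covariation between expression and multiple
  marks seen in real RNA-seq.
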
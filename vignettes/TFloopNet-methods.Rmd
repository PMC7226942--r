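---
title: "TFloopNet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TFloopNet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the statistical machinery inside TFloopNet, the
parameters that matter, what the synthetic-fixture generator does and does
not emulate, and the places where the design was genuinely open and a
choice had to be made.

## The problem

Enhancer–promoter (EP) chromatin loops are bound by cooperating sets of
transcription factors (TFs). The pipeline asks: which TFs co-operate, how
is that cooperation organised vertically (hierarchy) and horizontally
(communities, cliques), how does it change between cell lines, and which
genes does each cooperating set regulate? Three data views are combined:
linear-genome co-binding of ChIP-Seq peaks (1D), motif occupancy of loop
anchors plus protein–protein interaction evidence (3D), and expression.

## Loop processing

Contact lists (BEDPE plus a tag-count column) are annotated with chromatin
states by ≥1 bp interval overlap; a loop is kept when its tag count is
strictly greater than `min_tags` (default 5, i.e. "more than five tags")
and one anchor carries an enhancer-class state while the other carries a
promoter-class state, in either orientation. State classes are
configurable substring vocabularies (`"Enhancer"`; `"Promoter"`, `"TSS"`)
because segmentation label sets differ between cell lines. Contact lists
from different antibodies are merged by exact anchor-coordinate equality;
tags add (evidence mass is preserved) and state label sets union. All file
coordinates are 0-based half-open BED; in memory everything is a `GRanges`.

## The 1D co-localization statistic

For a query peak $q$ of TF $a$ and the reference peak set $B$ of TF $b$ on
the same chromosome, define the gap distance
$d(q,B)=\min_{r \in B}\max(0,\ \mathrm{start}_r-\mathrm{end}_q,\
\mathrm{start}_q-\mathrm{end}_r)$ (overlapping or abutting intervals are at
distance 0). The placement p-value is the fraction of all start positions
in the domain at which an interval of $|q|$'s width lies at distance
$\le d(q,B)$; it is computed in closed form by merging the per-reference
admissible start ranges, and it equals exhaustive placement enumeration
exactly (property-tested on random instances). The domain defaults to the
full chromosome extents implied by the peak compendium; a domain BED
restricts it. Queries on chromosomes without references get $p=1$ rather
than being dropped.

The similarity $s(a\to b)$ is the fraction of $a$'s peaks with $p <
\alpha$ ($\alpha=0.05$, strict). Each TF is a query set exactly once
against every other TF, giving an asymmetric matrix; with 237 peak sets
this is $237\times236 = 55{,}932$ ordered pairs. The direction overlay
used later by the hierarchy stage keeps $a\to b$ iff
$s(a\to b) > s(b\to a)$ and drops exactly tied pairs; this operationalizes
"the direction in the 1D matrix", which admits no unique reading — the
asymmetry sign is the only quantity available from the matrix itself.

## Motif occupancy of anchors

PWM scanning scores every window on both strands with log-odds bits
against a background model (default uniform; pseudocount 0.1 distributed
by background). The null p-value is exact: the per-position score
distribution is discretized in `score_bin` = 10⁻³ bits and convolved by
dynamic programming, so the tail probability at the observed (binned)
score is exact up to a score error bounded by width × bin. Windows
containing `N` are skipped. The default per-site threshold is 10⁻¹⁰; note
a width-$w$ motif cannot reach $p<4^{-w}$, so thresholds of 10⁻¹⁰ require
$w \ge 17$ — the fixture generator therefore plants width-18 consensus
motifs.

List A contains TFs with at least one significant occurrence in an
enhancer-class anchor. On the promoter side (a PASTAA-style association
test) anchors are ranked by the TF's best per-anchor score and the
minimal hypergeometric tail over all ranking cutoffs is taken, with the
positives being the promoter anchors that carry a significant occurrence.
A TF enters list B when that minimal p is below `enrich_alpha` (0.05), or
when every promoter anchor is positive (the hypergeometric is powerless at
saturation; presence everywhere is presence). The final list is
$A \cap B$. The set-level reading of promoter enrichment was chosen over a
per-promoter call because only the aggregate decision (is this TF a
promoter-side binder in this cell?) feeds the 3D matrix. The scan
threshold can be optimized across cell lines on a grid from 10⁻⁷ to 10⁻¹³
by the discrete inflection (largest |second difference|) of the mean
pairwise Jaccard of final TF lists; a flat curve falls back to 10⁻¹⁰.

## Fusion

The 3D adjacency keeps TF pairs supported by *both* databases: a STRING
record with score strictly above 400 and a BioGRID record with
experimental evidence. The 1D matrix is symmetrized by the arithmetic mean
of the two directions, both matrices are restricted to their shared TFs
and floored off-diagonally at `eps` = 10⁻³ (so isolated rows remain
stochastic), and similarity network fusion runs for `t` = 20 iterations:
each view's full transition kernel (off-diagonal mass ½, diagonal ½) is
diffused through the other view's row-normalized K-nearest-neighbour
kernel ($P_1 \leftarrow S_1 P_2 S_1^\top$, simultaneous update,
symmetrized each iteration), and the fused matrix is the average of the
two diffused kernels. K defaults to $\max(2, \lfloor n/10\rfloor)$. The
paper trail for these free parameters is empty, so the conventional SNF
defaults are fixed and logged. Neighbourhoods are value-defined (ties with
the K-th largest affinity are all kept) so fusion commutes with node
relabeling even on binary matrices. Cross-diffusion mixes entries by
construction: fusing a matrix with itself preserves the strong/weak
backbone contrast but *not* the exact off-diagonal entry ranking, and the
test suite asserts the former. The fused matrix is binarized strictly
above the mean off-diagonal weight (a quantile rule is available); the
directed overlay is the 1D direction set restricted to kept edges.

## Hierarchy

For a level assignment (level 1 = top) the raw hierarchy score is the mean
edge-direction sign, $HS = \frac{1}{|E|}\sum_{u\to v}
\mathrm{sgn}(\ell(v)-\ell(u))$, so $HS \in [-1,1]$ and reversing the level
order negates it. The corrected score standardizes $HS$ against random
permutations of the level labels across nodes with level sizes preserved.
By exchangeability the permutation mean is exactly 0; the permutation
variance is computed *exactly* from the 2-, 3- and 4-node sign moments of
the label multiset together with structural pair counts of the edge list
(shared-tail, shared-head, head-to-tail, disjoint). A sampled estimator
(`method = "sampled"`) is retained and agrees with the exact moments; the
exact form removes Monte Carlo noise from model selection, which matters
because nested level counts often share the same optimal raw score and
differ only through the null standard deviation.

Level counts 2…8 are searched by simulated annealing (single-node
relocation moves, Metropolis acceptance on the corrected-score change,
geometric cooling, `restarts` independent restarts of
`steps_per_node`·n moves each; all seeded). The level count with the best
corrected score wins; per-node level frequencies across the winning
restarts quantify assignment ambiguity and the modal level is reported.
Link ratios between levels divide observed undirected links by $n_i n_j$
(off-diagonal) or $n_i(n_i-1)/2$ (within level).

## Communities, cliques, coherence

Communities grow greedily from unused seeds in decreasing degree order
under the cohesiveness objective $f(V) = w_{in}/(w_{in} + w_{bound} +
p\,|V|)$ with penalty $p=2$; grown sets merge when the overlap score
$|A\cap B|^2/(|A||B|) \ge 0.8$ and are kept at size ≥ 3 and edge density
≥ 0.5 (the conventional defaults of this algorithm family; the paper
prints none). Communities may overlap. Maximal cliques come from
Bron–Kerbosch with pivoting, filtered to sizes 3…10, and are compared
across cell lines by exact member-set equality. A gene is "regulated by a
clique" when some EP loop has a promoter anchor overlapping the gene's
TSS and every clique TF has an occurrence in that loop's anchors — the
source text never defines this rule, so this reconstruction errs on the
conservative (all-TFs-present) side; it is antitone in clique size by
construction. Shared-clique patterns across cells classify as same
clique/same genes (gene Jaccard ≥ 0.9), same clique/different genes, or
partial TF sharing (≥ 3 shared TFs). Expression coherence compares
Spearman correlations of within-clique TF pairs against never-co-occurring
pairs with a one-sided Wilcoxon rank-sum test (exact where `stats::wilcox.test`
is exact, which matches full enumeration for small samples).

## Biclustering

The binary clique×gene matrix is factorized as $X \approx \Lambda Z$ with
an L1 penalty on both sides, fitted by alternating proximal-gradient
sweeps (each sweep's step is bounded by the current Gram trace, so the
penalized loss $\tfrac12\|X-\Lambda Z\|_F^2 + \lambda(\|\Lambda\|_1 +
\|Z\|_1)$ is non-increasing — this penalized loss, not the raw
reconstruction error, is the monotone quantity under soft-thresholding).
Defaults: 10 factors, up to 10,000 sweeps, convergence at relative loss
change < 10⁻⁶. Initialization is the truncated SVD followed by a varimax
rotation, making fits deterministic. The matrix is fitted *uncentered*:
column-centering a 0/1 incidence matrix injects a rank-one background that
makes disjoint planted blocks non-orthogonal, and the factor basis then
mixes them into ± contrasts whose supports are unions of blocks — with the
uncentered matrix, disjoint blocks are exactly orthogonal and separate
perfectly. Superclique/gene-group membership takes |loading| above the
per-factor 0.9 quantile, floored at half the factor maximum; the floor is
needed because a bare quantile returns everything when a factor is near
zero and (through ties) nothing when a block holds more than 10% of the
rows. Edge weights of the superclique–gene-group graph count regulated
(clique, gene) pairs between the two sets.

## The synthetic fixtures

The generator's defaults define the reference study conditions: a 2×1 Mb
genome, 12 TFs, 60 loops (60% EP, tag counts 6–30), 500 bp anchors, 200 bp
peaks, width-18 implanted consensus motifs (PWM: 0.91 on the consensus
base), one planted co-localizing pair mirrored within 50 bp at 90%
sharing, two planted communities each containing one planted triangle
clique, three planted hierarchy levels of four TFs with 95% of influences
pointing downward, five expression replicates per cell line (noise sd 0.1
around a per-clique latent profile), and two planted clique×gene blocks in
a 12×60 matrix. Upward noise influences are planted only across ≥ 2
levels, with a conflicting downward two-step path guaranteed through an
intermediate level: without that constraint an adjacent-level flip leaves
the influence graph acyclic, and a *finer* hierarchy genuinely attains a
higher corrected score than the planted one — recovery failure would then
be the correct inference rather than a defect. Sizes were chosen so the
full suite and the acceptance script run in minutes on one CPU; the
vignette's problem sizes are the package's reference conditions, not
empirical claims.

What the fixtures do not emulate: read-level noise, peak-caller artifacts,
degenerate (information-poor) motifs, inter-chromosomal loops, antibody
biases, or realistic PPI false-negative structure. Passing tests therefore
demonstrate correctness of the algorithms against planted truth, not
performance on real data.

## Known limitations

* The corrected hierarchy score reconstructs the cited
  hierarchy-score-maximization idea from its description (mean direction
  sign, permutation standardization); the original's exact formula is not
  public in the source text.
* The promoter-side enrichment is a minimal-hypergeometric stand-in for
  PASTAA's affinity association statistic.
* Exact-equality loop merging ignores near-duplicate anchors; a tolerance
  window is a natural extension and deliberately not default.
* The biclustering model is a sparse factor analysis of the same model
  class as FABIA's multiplicative model, not its variational estimator.
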
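---
title: "Phylogenomic distances, species delineation and character conservation with gbdphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenomic distances, species delineation and character conservation with gbdphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbdphylo)
```

## The analysis this package implements

Modern prokaryotic taxonomy rests on whole-genome comparisons. A
practical and widely used route is distance-based: compute a pairwise
intergenomic distance from local-alignment hits between genomes or
proteomes, build a tree from the distance matrix, convert the distances
into digital DNA-DNA hybridization (dDDH) estimates, and delineate
genomic species at the classical 70% DDH boundary. Around that backbone,
taxonomists ask two further questions: which phenotypic and genomic
characters track the genome phylogeny (phylogenetic conservation), and
how congruent are trees built from different markers (single genes,
concatenates, whole genomes)? `gbdphylo` implements this whole loop as
composable R functions plus a one-call pipeline, together with a
simulator that provides ground truth for every stage.

## Intergenomic distances from ungapped hits

Two proteomes are compared by exact $k$-mer seeding ($k = 6$ for
protein, 11 for DNA) followed by ungapped extension in both directions
under BLOSUM62 (or +1/−2 for DNA). Extension stops when the running
score drops more than the X-drop threshold ($X = 20$) below the best
score seen, and the hit is the maximal-scoring stretch. Hits shorter
than `min_len` (10) or scoring below `min_score` (30) are discarded.
This seed-and-extend scheme is the deterministic, desk-scale counterpart
of a BLAST HSP search; it is oracle-checkable (the tests compare it
column-for-column against an exhaustive ungapped Smith–Waterman scan)
but makes no attempt to replicate BLAST byte-for-byte.

Overlapping hits would count the same residues twice, so hits are
trimmed greedily: in descending score order, each accepted hit claims
its query and subject intervals and later hits lose any claimed column;
surviving fragments shorter than `min_len` are dropped and their
mismatch counts recomputed column-by-column. After trimming, with
$N = \sum_i N_i$ non-identical residues over $L = \sum_i L_i$ aligned
columns, the distance is the log-transformed mismatch ratio

$$d = -\ln\left(1 - \frac{N}{L}\right),$$

which is 0 for identical genomes, grows without bound as proteomes
diverge, and is approximately linear in divergence when $N/L$ is small.
The raw ratio $N/L$ is reported alongside. A pair with no surviving
hits has an undefined distance; `distance_matrix()` substitutes a
configurable ceiling (`d_max = 5.0`, with a warning) so matrices stay
finite for tree building, which mirrors what saturation does to real
single-gene comparisons.

Branch support comes from a pseudo-bootstrap: each pair's trimmed hits
are resampled with replacement (keeping the hit count), the distance is
recomputed from the resampled totals, and trees are rebuilt; the default
is 100 replicates.

## dDDH and species delineation

The dDDH mapping must be monotonically decreasing with $d$, equal 100%
at $d = 0$, and cross the recommended 70% species boundary at a stated
distance. The default is the two-parameter exponential decay
$\mathrm{dDDH}(d) = 100\,e^{\lambda d}$ with
$\lambda = \ln(0.70)/d_{70}$, anchored at $d_{70} = 0.09$ — the
screening distance below which strain pairs are close enough that a DDH
comparison is warranted. Published regressions of wet-lab DDH on
intergenomic distance can be substituted by passing any function
`d -> percentage` as `mapping`; the default anchored decay was chosen
because the regression constants of the reference web service are not
part of this package. Species are the connected components of the graph
joining strain pairs with dDDH at or above the threshold, making
conspecificity transitive, as `delineate_species()`'s tests verify
against an independent graph library.

## Tree inference

`nj_tree()` is a textbook neighbor-joining implementation with two
deliberate details: ties in the Q-criterion are broken by the
lexicographically smallest (sorted) label pair, so results are
reproducible across platforms, and negative branch-length estimates are
clamped to zero. `bme_refine()` then hill-climbs under the balanced
minimum evolution criterion — the published objective of FastME — using
Pauplin's weighting
$L(T) = \sum_{i<j} 2^{\,1-p_{ij}} D_{ij}$ (with $p_{ij}$ the number of
edges between tips $i$ and $j$), visiting internal edges in a fixed
order, accepting the first nearest-neighbor interchange that strictly
lowers $L$ and sweeping until a local optimum. The FastME binary itself
is not wrapped; implementing the criterion keeps the computation fully
inspectable and testable (the refiner provably restores single-NNI
perturbations of additive matrices). After a topology change, branch
lengths are re-estimated by least squares. Trees are reported unrooted;
outgroup or midpoint rooting is a display decision left to the user.

## The tip-permutation test of phylogenetic conservation

For each character, the observed tip-to-value arrangement is
parsimony-scored on the genome tree; the tip labels are then shuffled
uniformly at random $M - 1$ times (default $M = 10{,}000$ arrangements
including the identity) and rescored, and

$$p = \frac{\#\{\text{arrangements with score} \le \text{original}\}}{M}.$$

The identity arrangement always counts, so the smallest attainable $p$
is $1/M$. The same permutation stream is shared across characters,
which makes results reproducible and p-values comparable within a run.
Binary and unordered characters are scored with the Fitch count;
ordinal characters with the Sankoff dynamic program under linear cost
$|i-j|$ (ordered/Wagner parsimony); both run on one vectorized Sankoff
engine that handles multifurcations exactly and treats missing values
as zero-cost for every state. Continuous characters (proportions,
counts, percentages) are first discretized into $K = 10$ equal-width
bins over their observed range — a simple, transparent rescaling that
puts proportion and count data on a common ordinal footing; quantile
binning is available as an option, and $K$ is a flag. No
multiple-testing correction is applied by default: results are reported
as raw p-values against the conventional 0.01/0.05/0.10 lines, with
Benjamini–Hochberg flagging available in the chi-squared screen.

Because parsimony scores are integers, the permutation p-value is
slightly conservative when many arrangements tie; with 10 bins and
trees of a dozen or more tips, the score distribution is rich enough
that the test is calibrated in practice — the acceptance checks verify
that no-signal characters reject at close to the nominal 5% rate, and
that Brownian characters with $\sigma^2 = 4$ on a unit-depth tree score
systematically lower p than noise.

## Tree congruence and principal coordinates

`rf_distance()` compares unrooted trees through canonical bipartitions
(the block not containing the alphabetically smallest tip). Three modes
are reported: the plain Robinson–Foulds symmetric-difference count; the
relative distance, normalized by the total number of informative splits
in both trees so that it lies in $[0,1]$ (for fully resolved $n$-tip
trees this equals the usual $2(n-3)$ normalization); and the
bootstrap-weighted relative distance, in which every split is weighted
by its support, i.e. summed supports of splits unique to either tree
over summed supports of all splits. The exact weighted formula of other
implementations is not restated anywhere accessible, so this
support-sum normalization is adopted and documented, with the plain and
relative modes always available alongside; with uniform supports the
weighted and relative variants coincide exactly. Supports given on a
0–1 scale are auto-rescaled to 0–100. The tree-by-tree distance matrix
is embedded by classical metric scaling (double-centering the squared
distances and eigendecomposing); negative eigenvalues are reported but
excluded from coordinates.

## Chi-squared screening of binary features

Associations between binary phenotypic features are tested with
Pearson's chi-squared on the 2×2 table, after pairwise deletion of
missing values so each pair keeps its maximal sample size. No Yates
continuity correction is applied by default — the default is documented
and tested both ways, since conventions differ — and tables with a zero
margin are flagged degenerate rather than tested.

## What the simulator emulates, and what it does not

`simulate_tree()` draws Yule pure-birth trees: with $k$ lineages the
process waits $\mathrm{Exp}(k\lambda)$ and splits a uniform lineage,
adding one final waiting time at $n$ tips, so the expected root-to-tip
depth is $\sum_{k=2}^{n} 1/(k\lambda)$ — a property the tests check by
Monte Carlo. `evolve_proteomes()` evolves a root proteome of uniform
random 20-letter sequences along the tree: substitutions arrive as
Poisson events at uniform positions and always change the residue, so
the per-site identity between two tips at path length $t$ has the exact
closed form $1/20 + (19/20)e^{-(20/19)rt}$ used as a simulation oracle;
genes are lost by Poisson events and gained as fresh random sequences.
`evolve_characters()` provides binary Mk characters (symmetric 2-state
chain), continuous Brownian characters, and iid no-signal characters —
the null of the permutation test.

The simulator deliberately omits indels, rate heterogeneity, codon
structure, composition bias and horizontal transfer. Passing tests
therefore show that the pipeline's logic is correct under a clean,
analytically tractable model — not that real proteomes at real
divergences will behave as cleanly; in particular real BLAST-based
distances absorb gapped alignment effects this package does not model.

## Problem sizes and numerical choices

The packaged checks run at desk scale, chosen so the full suite
completes in minutes on one core: the topology-recovery study uses 50
runs of 10-tip trees with 60 genes of 200 residues
(12,000 aligned columns per pair) at substitution rate 0.1 per site per
unit branch length. At that depth the binomial sampling noise of the
mismatch ratio is roughly $5\times10^{-3}$ on $d$, well below the
typical internal-edge signal, and an a-priori power analysis puts exact
topology recovery in the mid-90s percent. The failures are essentially
all trees whose shortest internal edge is of order $10^{-3}$
substitutions per site — on such seeds even neighbor joining on the
exact realized per-site distances picks a wrong resolution, so no
refinement of the distance estimator can recover them; under a Yule
prior on 10-tip trees roughly one tree in twenty is of this kind.
Observed recovery on a fixed 50-seed panel is therefore expected to
fluctuate between about 90 and 98%. A second, smaller effect is that
ungapped hits at the deepest simulated divergences (mismatch fractions
above 0.5) cover only 65–80% of the proteome and sit preferentially in
conserved stretches, compressing those distances by a few percent; this
is inherent to hit-based distances and too small to change tree
topology except on already-marginal edges. Calibration of the
permutation test uses 1,000 no-signal characters with $M = 2000$ on a
16-tip unit-depth tree. Parsimony correctness is checked exhaustively
against enumeration over all internal-state assignments on all 105
labelled 6-tip topologies (binary) and all 15 labelled 5-tip topologies
(ternary, linear cost).

Other numerical conventions: distances are validated symmetric within
$10^{-12}$ and exactly symmetrized on file read (asymmetry beyond
$10^{-6}$ is an error); BME improvement must exceed $10^{-12}$ to be
accepted, so tie cycles cannot occur; equal-width binning maps the
column maximum to the top state and constant columns to state 0;
missing character values are encoded `NA` throughout.

## Known limitations

The hit finder is exact-seed and ungapped, so at high divergence
(roughly beyond 0.5 substitutions per site) pairs lose seeds, hits fail
score thresholds, and distances saturate toward the `d_max` ceiling —
the simulator's noisy "single-gene" trees exploit exactly this
behavior. The dDDH default mapping is anchored, not regressed against
wet-lab DDH, so printed dDDH values from regression-based services are
reproduced only by plugging in their published mapping. The BME search
is NNI-only (no SPR), matching the refinement stage it emulates, and
can in principle stop in a local optimum on pathological matrices.
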
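---
title: "Semi-supervised ontology inference from heterogeneous gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised ontology inference from heterogeneous gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontonet)
```

## The problem

Gene Ontology (GO)-style ontologies are curated by hand, which leaves gaps
and inconsistencies. Molecular networks — co-expression, genetic
interaction, functional association, physical interaction — carry enough
signal to infer parts of such ontologies automatically: a hierarchy of
gene clusters extracted from an integrated network can be read as a DAG of
candidate terms. The catch is that heterogeneous networks have wildly
different edge-weight semantics and distributions, and an unsupervised
integration (e.g. summing min-max-scaled weights) implicitly assumes all
networks are equally and uniformly informative, which real data violate.

`ontonet` implements a semi-supervised alternative. A trusted sub-tree of
an existing ontology (the *training part*) supervises three steps: which
edges of each network to keep, how to discretize each network's weights
onto a common ordinal scale, and how to weight the networks' levels in a
single integrated network. The integrated network feeds a
clique-extraction procedure (CliXO-style) that builds a DAG of candidate
terms, which is finally evaluated against the reference ontology on the
parts *not* used for training.

## The pipeline, step by step

**1. Training part.** Every term whose level (shortest path to the
namespace root, root = level 1) lies between 2 and 5 roots a candidate
training sub-tree (`selectTrainingSubtrees()`). A sub-tree plus its
descendants defines the training genes.

**2. Training similarities.** For training genes $g_a, g_b$ the
similarity is a normalized simplified Resnik measure,
$$\hat s_{ab} = \frac{-\log(|G_{LCA}| / |G_{tot}|)}{-\log(1 / |G_{tot}|)},$$
where $|G_{tot}|$ is the number of training genes and $|G_{LCA}|$ the
number annotated by the most informative common ancestor term of the
pair, all within the training part. Scores lie in $[0,1]$; pairs scoring
at least $t_s = 0.3$ are *semantically similar*. The default $t_s$
roughly says "the pair shares a term annotating at most
$|G_{tot}|^{0.7}$ genes", which is how a fixed threshold stays meaningful
across training parts of different sizes.

**3. Filtering.** Each network learns a weight threshold $t_w$: scanning
the distinct training-edge weights downward, $t_w$ is the smallest
weight at which at least half of the retained training edges are
semantically similar (`learnThreshold()`). If that requirement looks
hopeless — the similar fraction fails to increase over five consecutive
reductions before ever being met — the scan stops and falls back to the
weight before those reductions. Only training pairs vote; the threshold
then filters *all* edges.

**4. Discretization.** Filtered weights are discretized into ordered
levels so that different networks become comparable without destroying
each network's weight ordering (`searchDiscretization()`). The objective
is *discordance*: over unordered pairs of training pairs, the number
whose ordering by level disagrees with their ordering by ontological
similarity, with the direction function $d(x,y) \in \{-1, 0, 1\}$.
Order preservation is a hard constraint — a higher original weight can
never get a lower level, and equal weights share a level. The search is
annealing-like: random order-preserving start with $k = 200$ levels,
block moves of 1–5 equal-weight groups between adjacent levels, 10,000
iterations, non-improving moves accepted with probability
$\min\{0.1/\text{iteration}, 0.001\}$, five restarts, best map kept.
Because equal-weight groups are the atomic units, moves operate on
groups; the proposal picks 1–5 top or bottom groups of a random level.
Internally the objective is maintained incrementally through a
precomputed group-pair matrix, so a move costs time proportional to the
affected levels only; a full recount cross-checks the incremental value.
Finally adjacent levels are merged down to 10–20 (greedily, cheapest
discordance increase first; ties to the smaller pair, then the lower
one) to avoid over-fitting downstream, and every edge — training or not —
receives its level's representative weight (the mean of member training
weights, half-open boundary intervals anchored at training weights).

**5. Integration.** A $|T| \times N$ design matrix pools all networks'
merged levels ($N$ = total level count); entry $(i, j)$ is pair $i$'s
discretized weight if its edge occupies level $j$, else 0. The
coefficient vector maximizing the Pearson correlation of $Ma$ with the
training similarities is the single-response special case of canonical
correlation analysis and has the closed-form least-squares solution on
centered columns (`fitIntegration()`; unit-norm, sign fixed so the
correlation is non-negative; a $10^{-8}$ ridge catches rank-deficient
designs). The pipeline's default uses the projected non-negative variant
of this solver: with desk-scale training sets (a few hundred pairs
against 30–60 level columns) the unconstrained fit can overfit and
assign sign-flipping coefficients that scramble the edge ordering the
clique extraction depends on; clamping to the non-negative orthant is
the mildest stabilizer that preserves the closed-form solution when it
is already non-negative. `fitIntegration()` itself defaults to the
unconstrained fit. The integrated weight of an edge is
$\sum_{\text{networks}} a_{\ell} \cdot w_{\ell}$ over the levels it
occupies, min-max rescaled to $[0,1]$.

**6. DAG inference.** `inferDag()` sweeps the distinct integrated
weights downward. At threshold $t$ an edge counts as present if its
weight is at least $t - \alpha$ ($\alpha$ absorbs noise). Starting from
singleton terms, current top-level terms merge into a new parent term
when their combined gene set's subgraph has at most a fraction $\beta$
(default 0.5) of its edges missing. Candidates are maximal cliques
(Bron–Kerbosch with pivoting) of the graph connecting density-compatible
term pairs, processed largest gene set first with lexicographic
tie-breaks; within a sweep round each term joins at most one new parent,
which keeps batches of simultaneously-arriving equal weights from
spawning a combinatorial explosion of overlapping near-duplicates.
Duplicate gene sets are never re-created — later candidates link to the
existing term instead, which is how terms acquire multiple parents and
the result becomes a DAG rather than a tree. Children are always strict
subsets of parents, and the structure is acyclic by construction
(validated on every object).

**7. Alignment and evaluation.** Two DAGs align greedily by descending
Jaccard similarity of their term gene sets (*intrinsic* similarity only
— no term names, no hierarchy context), one-to-one, with crisscrossing
pairs (ancestor/descendant order inverted between the DAGs) forbidden.
A permutation null — gene labels of the first DAG shuffled, the whole
matching re-run — calibrates a score cutoff: the smallest score at which
expected null matches over observed matches drops to the 5% FDR. Terms
annotating more than half the shared gene universe are excluded before
matching: a size-preserving label permutation reproduces near-universe
terms almost exactly, so they carry no intrinsic information and would
otherwise swamp the null (the same logic that motivates $t_s$).

Held-out evaluation mirrors the training/test split: an all-genes DAG
$O_G'$ and a training-genes-only DAG $O_T'$ are inferred, and any
$O_G'$ term aligned to $O_T'$ counts as *training-derived*. Aligning
$O_G'$ to the reference ontology, `evaluateAlignment()` reports
$\mathrm{Hit}$ (aligned pairs with the reference term outside the
training part and the inferred term not training-derived), precision
(over inferred terms net of training-derived), recall (over reference
terms outside the training part, within the alignable size window) and
their harmonic mean F. Headline comparisons between integration
strategies average F over the alpha grid and over all level-2 training
sub-trees, since any single training part's score carries substantial
sampling noise at this scale.

## The synthetic world

`generateWorld()` plants a known ontology and emits noisy network views
of it, so every stage has ground truth:

```{r world}
world <- generateWorld(seed = 1)
world
```

The defaults are the package's canonical study conditions: 60 genes on a
depth-4, branching-3 tree (root, 3 sub-trees of 20 genes, 9 mid-level
terms of ~7 genes, 27 leaf terms of 2–3 genes; 10% of deeper terms get a
second parent so the DAG is not a tree), and three networks whose edge
weights are monotone transforms of the true pairwise similarity —
identity and square transforms with additive Gaussian noise (sd 0.3,
clipped to $[0,1]$), plus a binary network thresholded at similarity 0.3
after noising. 30% of edges are dropped at random to emulate
incompleteness. The binary network goes through a diffusion kernel
($\exp(-\tau L)$ on the normalized Laplacian, $\tau = 1$, off-diagonals
scaled into $(0,1]$) before integration, the standard way to turn a
binary interaction graph into graded connectivity weights.

The branching factor matters more than it looks: it sets the size of
mid-level terms relative to the training part, and with $t_s = 0.3$ the
"semantically similar" band covers pairs sharing terms up to roughly
$|G_{tot}|^{0.7}$ genes. Branching 3 keeps the mid-level terms inside
that band (as moderate-size terms are in a real GO), so the learned
filter retains the structure the evaluation asks about. The generator
emulates monotone signal, heterogeneous distributions, noise and
missingness; it does not emulate realistic network topology (degree
distributions, motif structure), hub artifacts, or correlated noise
between networks — conclusions from these tests are about the pipeline's
mechanics, not about any particular organism's data.

## A short run

```{r run, eval = FALSE}
res <- runPipeline(world, seed = 1)
res$metrics
# benchmark arms
runBenchmarkSummation(world, seed = 1)$meanF
runSingleNetwork(world, which = 1, seed = 1)$meanF
```

`runPipeline()` returns the per-alpha metric table (the alpha grid
defaults to 0, 0.05, 0.1, 0.2, 0.3 in integrated-weight units, spanning
high-precision to high-recall regimes), the fitted coefficients, filter
and discretization reports, and the integrated network; `outDir` writes
everything as tab-separated files plus a manifest.

## Numerical and design choices

* **Logarithms** in the similarity are natural; the normalized ratio is
  base-invariant.
* **Genes with no common training ancestor** score 0 (cannot happen for
  well-formed training parts, where the training root is shared).
* **Equal-IC ties for the LCA** need no tie-break: only the IC value
  enters the score.
* **Discordance counts unordered pairs**; the indicator is symmetric, so
  ordered counting would merely double every value.
* **The threshold scan's two stopping rules** interact as follows: the
  scan always visits every distinct training-edge weight and keeps the
  smallest satisfying one; the five-non-increase patience only ends a
  scan early when nothing has satisfied the requirement yet, and then
  the pre-slump weight is the fallback. The patience is a parameter of
  `learnThreshold()`.
* **Degenerate searches** (all weights equal) return a single level
  immediately. All-equal similarities make every partition optimal; the
  search returns one with objective equal to the direct count.
* **CliXO parameters**: $\beta = 0.5$ throughout; $\alpha$ is swept, not
  fixed, because it trades precision against recall. This implementation
  follows the published characterization of clique-extracted-ontology
  construction ($\alpha$ = edge-inclusion margin, $\beta$ = tolerated
  missing-edge fraction), not any specific binary's internals.
* **Alignment FDR** uses 100 label permutations by default; matched
  pairs of the permuted problem form the null. Greedy matching (not
  globally optimal assignment) keeps the procedure deterministic and
  fast; ties break toward the smaller inferred term, then
  lexicographically.
* **Problem sizes** in the test suite — 60-gene worlds, 50-instance
  oracle sweeps, 100-permutation nulls — were chosen so the whole suite
  and the acceptance script run comfortably on a laptop while leaving
  each property enough resolution to fail visibly when broken.

## Known limitations

* The per-level integration fit has one free coefficient per merged
  level; with very small training sets it can overfit even with the
  non-negative constraint, and the benchmark summation arm is then a
  serious competitor. At realistic scales (thousands of training pairs)
  this vanishes. Relatedly, held-out F comparisons between arms on a
  60-gene world carry substantial seed-to-seed variance; single-seed
  margins should be read qualitatively.
* Filtering keeps only the top weight band of each network, so ontology
  levels whose gene pairs live below $t_w$ are invisible downstream —
  the price of removing irrelevant edges, exactly as in the real
  pipeline.
* The clique sweep is quadratic in the number of current terms per
  threshold and is meant for networks of up to a few hundred genes;
  `maxDegree` guards pathological inputs.
* `loadOntology()` reads the OBO 1.2 subset it documents (is_a, part_of,
  obsolete flags, alt_ids); qualifiers, regulates-relations and
  cross-products are out of scope.
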
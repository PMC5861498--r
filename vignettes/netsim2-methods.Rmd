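---
title: "Methods: network-aware GO semantic similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-aware GO semantic similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsim2)
```

## The problem

Gene Ontology (GO) semantic similarity asks how functionally alike two
genes are, given where their annotated terms sit in the ontology DAG and
which genes those terms annotate. Annotation-only measures inherit the
gaps of GO curation: for sparsely annotated species most gene pairs look
uninformatively dissimilar. The NETSIM2 measure implemented here
compensates with a second evidence source, a weighted gene co-functional
network, and uses its **global** topology — not just direct edges — via a
random walk with restart (RWR). Because propagating network signal also
imports noise, the gene-level aggregation keeps only statistically
significant term pairs.

## Model and assumptions

### Random-walk relevance

The network is undirected with nonnegative weights; duplicate edges keep
the maximum weight, self-loops are dropped, and a gene left with no edge
is excluded from the walk (it falls back to the maximal distance of 1).
The transition matrix is column-stochastic, `M′[i,j] = M[i,j]/Σ_k M[k,j]`,
which guarantees `(I − cM′)` is invertible for any continuation
probability `c < 1` and that each relevance row is a probability
distribution. Two solvers share one contract: a dense closed form
`r_i = (1−c)(I − cM′)⁻¹e_i` for networks up to 2000 genes, and a power
iteration stopped when the per-start L1 change falls below `tol` (its L1
error against the closed form is at most `tol/(1−c)`). The walk on a
weighted graph is asymmetric, while the downstream gene-set distance
treats `d_ij` as symmetric; we therefore symmetrize `R ← (R + Rᵀ)/2`
before forming `d_ij = 1 − R_ij`. Stationary probabilities are not
rescaled beyond that — only term-level gene-set distances are normalized.

The restart probability defaults to 0.3 (`c = 0.7`), the common choice in
network-propagation methods; every structural property holds for any
`c ∈ (0,1)`, and `restart → 1` is the documented "network-off" ablation
in which all cross-gene distances converge to 1.

### Term similarity

Annotations are propagated by the true-path rule across `is_a` and
`part_of` edges alike — these are the only edge types the DAG keeps, and
nothing in the measure distinguishes them for gene transfer, so a single
propagation rule is applied to both. Terms with empty propagated gene
sets stay in the DAG for structural queries but are excluded from
similarity (their set sizes would put a zero inside a logarithm).

The raw gene-set distance `D` compares two propagated sets through
products of pairwise gene distances; any shared gene zeroes its product,
so `D` vanishes on identical sets and its denominator
`2|G₁∪G₂| − Σ − Σ` is provably positive whenever all `d ∈ [0,1]`.
Products are evaluated in log space with an explicit `log(0) = -Inf`
short-circuit, so sets with thousands of genes cannot underflow. Raw
distances are min–max normalized **per run, per namespace**, over all
term pairs computed (the diagonal included, which pins the raw minimum at
0); the bounds are stored in the context so cached results remain
reproducible. If every raw distance is identical the span is degenerate
and all values map to 0, collapsing the measure toward its
annotation-only form — the conservative reading of an uninformative
network.

For a common ancestor `p`, the path-constrained annotation `U(t₁,t₂,p)`
replaces the full descendant closure of `p`: it unions the propagated
genes of `t₁` and `t₂` with the *direct* annotations of every term lying
on a directed path from either term up to `p` (inclusive of all three).
This always satisfies `G₁ ∪ G₂ ⊆ U ⊆ G_p`. The per-ancestor score

$$S_p = \frac{2\log|G| - 2\log f}{2\log|G| - (\log|G_1| + \log|G_2|)}
  \left(1 - \frac{h}{|G|}\cdot\frac{|G_p|}{|G|}\right)$$

uses natural logarithms; the left factor is a ratio of log-differences
and hence invariant to the base (unit-tested), and `G_p/G` is read as
the cardinality ratio `|G_p|/|G|` — division is only meaningful on set
sizes. When both terms annotate the whole genome the denominator
vanishes; such terms carry no information and the similarity is defined
as 0. A DAG pair can have several lowest common ancestors (a term counts
among its own ancestors, so the ancestor set is never empty); the
similarity is the maximum of `S_p` over all of them.

### Gene similarity and significant-pair selection

Per term `t`, similarities to all other usable terms form the background
`(μ_t, σ_t)` (population standard deviation; a seeded uniform subsample,
default cap 2000, bounds the cost on large ontologies). A candidate pair
is significant when `|z| = |S − μ_t|/σ_t > 1.6`, the constant printed
with this measure (not 1.645); it is configurable. The aggregation uses
each gene's **direct** annotations — propagated closures would drown
specific terms in their shared ancestors. For each term of one gene the
candidates of the other gene split into a high set (`z > 1.6`) and a low
set (`z < −1.6`); the larger is selected, a nonempty tie preferring the
high set (similarity aggregation favours informative matches; the source
formulation leaves this case open). If neither set is populated, the
single candidate with the largest `|z|` is used, so every term finds a
partner; with a zero-variance background the best raw similarity stands
in, keeping the gene similarity total. With selection disabled the
formula reduces to the classic best-match average — the aggregation used
by the measure's direct-link-only predecessor, retained as a regression
surface (`select = FALSE`).

### The EC benchmark

Genes sharing a complete four-field EC number are assumed functionally
similar. For gene `g` of group `e_i` and a disjoint group `e_j`, the
contrast is the log-ratio of mean smoothed distances; the implementation
computes it as `ln(mean(1 − sim + c) / mean(1 − sim + c))`, identical to
the size-factor form when no pair is missing, and the natural
generalization when pairs with undefined similarity are skipped (they are
counted, and a group whose genes are all unscorable is dropped from the
report). The "without g" restriction applies to both the group-size
factor and the within-group sum. The per-group LFC averages over genes,
then **unweighted** over every partner group that is gene-disjoint from
`e_i` — the normalizer counts exactly the partners actually averaged,
otherwise excluded groups would dilute the mean. The Laplacian smoothing
constant defaults to 0.001: small enough not to distort, large enough to
keep the logarithm finite at similarity 1. Reported scores are truncated
at 5, the conventional reporting bound for this statistic; note the cap
and the walk's continuation probability are unrelated parameters that
both happen to be called *c* in the measure's usual notation
(`restart` vs `c_smooth` here).

## The synthetic generator

`fixture_spec()`/`make_fixture()` emulate the structure of the real
inputs at desk scale: a single-rooted layered DAG (monotone primary
parents give clean clades; a 0.25-probability second parent keeps it a
true DAG), genes annotated clade-wise to leaf terms, a planted-partition
network, and EC groups. With `aligned = TRUE` the network modules,
annotation clades and EC groups are one and the same partition; with
`aligned = FALSE` annotations and EC groups are randomized against the
network, destroying the signal while preserving all marginal structure.

Defaults — 120 terms (80 leaves), 96 genes in 32 modules of 3, two leaf
annotations per gene, within/between edge probabilities 0.8/0.05 with
weights uniform on (0.5, 1), annotation noise 0.15 — were chosen to give
the benchmark at least 30 EC groups in an *informative* regime. The noise
rate matters: with perfectly clean clades, same-module genes carry
identical annotation sets, every within-group similarity saturates, and
every EC hits the reporting cap under the full measure **and** under the
network-off ablation, so the benchmark cannot rank anything. Reassigning
15% of annotations to arbitrary leaves mimics shallow or spurious
curation and keeps median LFC well below the cap while leaving the
planted signal clearly detectable.

What passing tests on these fixtures shows — and does not show. They
verify the algebra, the selection semantics, the benchmark's direction of
effect (network evidence raises LFC over the ablation on aligned data;
shuffled data centres on zero), and end-to-end determinism. They do not
emulate GO's term-degree distributions, annotation depth bias, or
realistic network degree distributions, so they support no quantitative
claim about any particular species.

```{r, message = FALSE}
fx <- make_fixture(fixture_spec(seed = 1))
model <- netsim2_model(fx$dag, fx$ann, fx$network, restart = 0.3)
glance(netsim2_lfc(model, fx$groups))
```

## Numerical choices, degenerate inputs, limitations

* Cycles in the ontology are an input error (a member term is named);
  multi-rooted namespace slices are rejected — the universe size `|G|`
  needs one root.
* GAF rows with a `NOT` qualifier, terms missing from the DAG, or
  malformed fields are skipped with counts; all evidence codes are kept
  unless an allow-list is given, since the measure itself prescribes no
  filter.
* The walk's iterative solver reports its last residual on
  non-convergence rather than returning a half-converged matrix.
* `z > 1.6 ⇔ p < 0.05` presumes an approximately normal background;
  the package neither enforces nor tests normality.
* Term-pair backgrounds are computed per namespace run; cross-namespace
  similarity is out of scope, as are `regulates`-type edges, GO slims and
  obsolete-term resolution.
* Problem sizes throughout the tests and the acceptance script (networks
  of ≤ 100 genes for solver agreement, the 120-term/96-gene benchmark
  fixture) were chosen so the full suite re-runs in about a minute; all
  scale knobs are exposed through `fixture_spec()`.

## Package shape

Containers (DAG, annotation map, network, relevance matrix, similarity
context, fitted model) are plain S3 lists, because graphs and matrices
are not naturally tabular; every user-facing result — term similarities,
gene similarities, backgrounds, the LFC report — is a tibble that chains
with the pipe, and the fitted model and report have `tidy()`, `glance()`
and `autoplot()` methods. The shell entry point `exec/netsim2` is a thin
wrapper over the exported functions.
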
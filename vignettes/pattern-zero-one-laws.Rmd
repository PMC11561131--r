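---
title: "Snowflakes and other patterns in random phylogenetic trees: exact counts, samplers, and 0-1 laws"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snowflakes and other patterns in random phylogenetic trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treepatterns)
```

## The problem

A binary phylogenetic tree on $n$ leaves is an unrooted tree whose leaves are
labelled $1,\dots,n$ and whose interior vertices all have degree 3.  A
*snowflake* is a local configuration: a central interior vertex $v$, its three
interior neighbours, six interior vertices at distance 2 from $v$, and twelve
hanging rooted subtrees.  Equivalently, an interior vertex is the centre of a
snowflake exactly when its edge distance to every leaf is at least 3.
Snowflakes matter in combinatorial phylogenetics because the trees containing
one are exactly the trees that are hardest to pin down with homoplasy-free
characters; the question this package makes computable is *how common* such
configurations are in random trees.

The answer is a 0-1 law: as $n \to \infty$, the fraction of trees containing a
fixed pattern tends to 1 when the pattern is *realizable* for the underlying
branching mechanism, and is identically 0 when it is not.  The package
implements both routes to this result:

* an **exact combinatorial route** — closed-form counts of trees, forests and
  snowflake centres, evaluated in exact big-integer arithmetic, giving the
  density of snowflake centres and its second moment explicitly; and
* a **branching-process route** — exactly-uniform samplers built from
  size-conditioned critical Galton-Watson (GW) trees, the Kesten size-biased
  tree as their local limit, and a degree-exact pattern-embedding engine,
  with seeded Monte-Carlo experiments exhibiting the dichotomy.

## Exact enumeration

With $B(n) = (2n-4)!/((n-2)!\,2^{n-2}) = (2n-5)!!$ unrooted binary trees,
$R(n) = B(n+1)$ rooted ones, and
$N(n,k) = (2n-k-1)!/((n-k)!\,(k-1)!\,2^{n-k})$ forests of $k$ rooted trees
partitioning $\{1..n\}$, the package evaluates every identity exactly:

```{r enum}
count_unrooted_binary(6)                  # 105 = 7!!
verify_forest_decomposition(10)$holds     # B(n+2) = sum k! N(n,k)
snowflake_pairs(12)                       # N(12,12) * 12!/(2^9 3!)
snowflake_density(12)                     # = E(X_12), in lowest terms
```

`snowflake_density(n)` is the expected number $E(X_n)$ of snowflake centres
of a uniform tree (pairs $(T,v)$ divided by $B(n)$), equal to the closed form
$4\,\frac{(2n-13)!}{(2n-4)!}\frac{(n-2)!}{(n-12)!} \sim n\,2^{-7}$; the
second-moment counterpart `W_density_closed_form(n)` (ordered pairs of
centres at distance $\ge 5$) equals
$16\,\frac{(2n-22)!}{(2n-4)!}\frac{(n-2)!}{(n-22)!} \sim n^2\,2^{-14}$ and is
cross-checked against the explicit path-decomposition summation
`W_by_summation(n)` for all $22 \le n \le 60$.  Both symmetry constants
($12!/(2^9 3!)$ and $22!/2^{16}$) are recomputed from the orbit-stabilizer
factorisation, never hard-coded.

Because these quotients of factorials exceed the exact range of doubles
almost immediately, all identity checking runs on an in-package exact
integer/rational layer (`xint`/`xrat`: sign + base-$10^6$ limb magnitudes,
schoolbook arithmetic, exact division that fails loudly on a nonzero
remainder).  Floating point appears only in the asymptotic evaluators
(`snowflake_density_float`, `W_density_float`), which use `lgamma` and are
intended for $n$ of order $10^4$ and beyond.

A numerical observation surfaced by the tests: the scaled snowflake density
$128\,E(X_n)/n$ is within $10^{-4}$ of its limit already at $n = 10^6$, but
the second-moment density $2^{14}\,W(n)/(B(n)\,n^2)$ — which involves 18
falling factors instead of 9 — reaches that band only around $n = 10^7$.  The
asymptotic-constant tests therefore evaluate the first at $10^6$ and the
second at $10^7$.

## Samplers

**Uniform trees.**  For the offspring law $X = d\cdot\mathrm{Bernoulli}(1/d)$
(critical, $P(X=0) = 1 - 1/d$), a GW tree conditioned on its vertex count is
uniform over ordered $d$-ary trees of that size, because every such tree has
the same probability $(1/d)^i(1-1/d)^{n-i}$.  `sample_conditioned_gw` draws
the conditioned tree *exactly* in linear time with the cycle lemma: an
exchangeable out-degree sequence with sum $n-1$ has exactly one cyclic
rotation that is a valid preorder word — the one starting right after the
first minimum of the Lukasiewicz walk.  For the two-point law the degree
multiset is deterministic, so no rejection whatsoever is involved; for
general finite-support laws the iid sequence is drawn by rejection on its sum
(the classical rejection-of-GW sampler is retained in the test suite as an
independent oracle).  Grafting a pendant leaf at the root, labelling the $n$
leaves with a uniform permutation and forgetting order and root turns this
into a uniform leaf-labelled $d$-ary tree (`sample_uniform_leaf_labelled`);
uniformity is tested exactly, by chi-square tests against the full list of
isomorphism classes produced by the exhaustive generators.

**Yule-Harding trees.**  `sample_yule_harding` grows the tree by repeatedly
attaching the next leaf to a uniformly chosen pendant edge — the shape
distribution shared by constant-rate birth-death models.  Attachment is
purely topological (edge subdivision; no branch lengths).  Labels are a
uniform permutation drawn independently of the shape: the Yule-Harding
labelled law is exchangeable, which the raw attachment order is not — using
attachment order as labels would, for example, never produce the rooted
3-leaf tree whose cherry is $\{1,2\}$.  The root split $n_1(T_n)$ is uniform
on $\{1..n-1\}$, which `yule_split_test` checks by chi-square.

**Kesten balls.**  The local limit of size-conditioned critical GW trees is
the Kesten tree: an infinite spine $v_1, v_2, \dots$ where $v_k$ receives
$X^*_k - 1$ independent GW subtrees, $X^*$ being the size-biased offspring
law ($P(X^*=k) \propto k\,P(X=k)$, exact rationals in-package).
`sample_kesten_ball(X, k)` samples the radius-$k$ ball exactly: the spine is
truncated at depth $k$ and each grafted subtree is *depth*-truncated to its
remaining budget (not size-truncated), so the ball's distribution is exact.
The position of the spine child among the $X^*$ child slots is not dictated
by the limit theorem (it is irrelevant for unordered functionals); uniform
placement is used so that ordered ball codes are also comparable.
`ball_tv_distance` estimates the total-variation distance between the ball
law of the conditioned tree and the Kesten ball on the empirical union
support — this biases TV slightly downward, which is why the radius is kept
small (the default experiments use radius 2, where the support is essentially
complete at $10^4$ replicates).

**RNG contract.**  All samplers use R's global RNG; every experiment driver
takes an explicit integer seed, sets it on entry and derives one child seed
per grid point or replicate stream via `child_seed(master, i)` (a fixed
linear-congruential map into $[1, 2^{31}-2]$), so each point is reproducible
in isolation.

## Pattern occurrence

A pattern (`pattern_tree`) is a finite tree whose vertices are *internal* or
*free leaves*.  Containment $T \supset \tau$ is degree-exact: an injective
adjacency-preserving map under which every internal vertex keeps its exact
degree (all host neighbours covered), free leaves unconstrained — each free
leaf stands for an arbitrary hanging subtree.  This is the semantics under
which (i) the snowflake definition, (ii) the realizability dichotomy and
(iii) the $d$-ary generalisation are simultaneously consistent; plain
subgraph containment would make non-realizable patterns (such as the 4-vertex
path with two adjacent degree-2 internal vertices) occur in binary trees,
contradicting the dichotomy.  Plain subgraph containment remains available
separately as `occurs_subgraph`, for exploration only.

`occurs` decides containment in polynomial time: the pattern is rooted at an
internal vertex, and feasibility of each pattern subtree against each host
subtree is decided bottom-up, with a bipartite perfect matching (Kuhn's
augmenting paths) coupling children; results are memoised per (pattern edge,
host edge) pair.  `brute_force_occurs` is the independent exhaustive oracle
(backtracking over injective maps, no matching machinery) and the test suite
proves the two identical on every host with up to 6 leaves (unrooted) or 11
vertices (ordered) against every pattern with up to 7 vertices and every
admissible role assignment.  Degree-1 pattern vertices may take either role:
a free leaf matches any hanging subtree, while an *internal* degree-1 vertex
matches only an actual host leaf — the strictest reading that keeps every
stated example consistent.

Realizability (`is_realizable`) asks whether $\tau$ can be rooted so that all
out-degrees lie in the support of $X$.  "Rooted" is ambiguous between rooting
at a vertex and rooting on an edge (the phylogenetic convention: subdivide
and root at the new degree-2 vertex); the two conventions genuinely differ —
the snowflake itself is only edge-realizable for the binary law — so both
flags are computed and reported, and nothing in the package silently prefers
one.

## Monte-Carlo experiments and the synthetic-data conditions

The experiment drivers tie the samplers back to the exact enumeration:

```{r mc}
m <- mc_mean_snowflake_centers(50, reps = 2000, seed = 1)
m$estimate
as.numeric(snowflake_density(50))   # exact value the estimate must bracket
```

All experiments are governed by a three-standard-error acceptance band
around the exact quantity (or, where the theory gives only a limit, by
monotonicity plus the exact bound $P(X_n = 0) \le 1 - 2^{-7}$ that follows
from $E(X_n)/n$).  The replicate counts used by the shipped checks —
$10^4$ for moment comparisons at $n \in \{12, 50, 100\}$, 500 per grid point
for the occurrence curves on $n \in \{50, 200, 1000\}$, $10^4$ ball draws per
law at $n = 2001$ for the local-limit diagnostic, $10^5$/$3\cdot10^4$ draws
for the 5-class and 15-class uniformity tests — were chosen so the bands are
a small fraction of the quantities being measured while the whole suite stays
comfortably runnable on a laptop core.

What the generators emulate — and what they do not.  The samplers produce
topologies only: uniform ("proportional to distinguishable arrangements")
trees and Yule-Harding shape distributions.  Real phylogenies carry branch
lengths, non-uniform shape biases from heterogeneous speciation/extinction,
and estimation error; none of that is modelled, so passing tests here say
nothing about any inference pipeline — they validate combinatorial and
probabilistic statements about the two classical null models.

## Numerical and design choices

* **Exactness boundary.**  Identities are checked in exact arithmetic, always;
  `lgamma`-based floats appear only in asymptotic evaluators at large $n$.
  Exact division raises an error on a nonzero remainder rather than rounding.
* **Degenerate inputs.**  The two-leaf tree (no interior vertex) and the
  single-vertex ordered tree are handled explicitly everywhere; `ball(t, 0)`
  is the root; patterns with no internal vertex are allowed only up to two
  vertices (one free leaf: any tree; two: any tree with an edge).
* **Canonical codes and ties.**  Isomorphism is decided by canonical strings:
  leaf-labelled trees are rooted at the interior vertex adjacent to leaf 1
  and child codes sorted bytewise (locale-independent radix sort); ordered
  trees use their preorder degree sequence, unordered rooted trees an AHU
  code.  Witness embeddings are made deterministic by trying host children in
  increasing id.
* **Truncation signalling.**  The unconditioned critical GW sampler is almost
  surely finite but heavy-tailed; `sample_gw` returns a distinct
  `gw_truncated` object beyond `max_vertices` instead of silently clipping.
* **Guard rails.**  The exhaustive enumerators refuse leaf counts whose class
  count exceeds $10^6$ unless forced; the brute-force matcher refuses hosts
  beyond 16 vertices.

## Known limitations

* Only finite-support offspring laws are supported, and non-critical laws are
  rejected by the Kesten sampler; exponential tilting to an equivalent
  critical law is out of scope.
* Pattern *counting* (beyond snowflake centres) and distance-stratified pair
  counts have no closed forms here; the second moment is bracketed, not
  computed, by `mc_second_moment_snowflake_centers`.
* Phylogenetic networks (and the blow-up construction that extends the 0-1
  law to level-$k$ networks) are out of scope.
* The TV diagnostic underestimates slightly on truncated supports; treat it
  as an upper-bound check at small radius, not a general-purpose distance.
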
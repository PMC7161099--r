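---
title: "Integrated likelihood of species phylogenies under a no-common-mechanism coalescent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated likelihood of species phylogenies under a no-common-mechanism coalescent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncmnet)
```

## The model

A rooted phylogenetic network on a taxon set is a rooted DAG whose nodes
are a root (in-degree 0), leaves (in/out 1/0, bijectively labeled by taxa),
internal tree nodes (in/out 1/&ge;2) and reticulation nodes (in/out 2/1).
Each edge carries a length in coalescent units (generations over effective
population size); each reticulation carries an inheritance probability
$\gamma$ on one parent edge and $1-\gamma$ on the other. A species tree is
the reticulation-free special case.

Under the multispecies network coalescent, one gene lineage enters the
network at each leaf and travels rootward; within an edge each pair of
extant lineages coalesces at rate 1, at a reticulation each lineage
independently follows a parent edge according to $\gamma$, and above the
root coalescence continues until one lineage remains. The probability of a
gene-tree *topology* $g$ is a sum over *coalescent histories*: assignments
of each coalescence of $g$ to a network edge, together with a routing of
every lineage segment through the reticulations it passes. Two histories
that differ only in routing are distinct — their $\gamma$ exponents differ.
For a history $h$, with $u_b, v_b$ the lineages entering and exiting edge
$b$,

$$\mathbf{P}(h \mid \Psi,\Lambda,\Gamma) \;=\; \frac{w(h)}{d(h)}
\prod_{b} \frac{w_b(h)}{d_b(h)}\, p_{u_b v_b}(\lambda_b)
\prod_{i} \gamma_i^{u_{b1_i}} (1-\gamma_i)^{u_{b2_i}},$$

where $p_{uv}(t)$ is the lineage-count transition probability of the
coalescent, $d_b = \prod_{k=v_b+1}^{u_b}\binom{k}{2}$ counts all sequences
of the $u_b - v_b$ pairwise coalescent events on edge $b$, and $w_b$ counts
those sequences compatible with the gene tree (linear orderings of the
assigned coalescences that respect gene-tree ancestry). The root is treated
as a virtual edge of unbounded duration: all remaining lineages coalesce
there, contributing the event-order factor $w/d$ but no $p$ term. The
surviving root lineage's routing through any reticulations above the last
coalescence is enumerated as part of the history; its routing choices sum
to one, so the pmf is unchanged, but each routing's $\gamma$ exponents are
accounted exactly.

## The no-common-mechanism integrated likelihood

The common-mechanism likelihood multiplies $\mathbf{P}(g_i \mid
\Psi,\Lambda,\Gamma)$ across loci with a single shared $(\Lambda,\Gamma)$.
The no-common-mechanism (NCM) model instead lets every locus evolve under
its own parameter values, drawn independently from priors:

* branch lengths: independent Exponential(rate) truncated to $(0,\tau]$,
  with rate 1 and $\tau = \infty$ (untruncated) as defaults;
* inheritance probabilities: independent Beta($a$, $b$), default
  Beta(2, 2).

Both integrals are analytic. Writing $p_{uv}(t) = \sum_{j=v}^{u}
e^{-j(j-1)t/2} f(u,v,j)$,

$$p_{uv}^{\tau} = \frac{1}{1-e^{-r\tau}} \sum_{j=v}^{u} f(u,v,j)\,
\frac{r}{j(j-1)/2 + r}\,\bigl(1 - e^{-(j(j-1)/2+r)\tau}\bigr),$$

with the obvious $\tau \to \infty$ limit, and each reticulation factor
integrates to $B(a+u_{b1}, b+u_{b2})/B(a,b)$ — for Beta(2,2) the factorial
form $6\,(u_{b1}{+}1)!\,(u_{b2}{+}1)!/(u_{b1}{+}u_{b2}{+}3)!$. Substituting
these into the history probability and summing over histories gives
$\mathbf{P}(g \mid \Psi)$, a function of the topology alone, and the
m-locus log-likelihood is $\sum_i \log \mathbf{P}(g_i \mid \Psi)$.

The practical payoff is in inference: the search walks the (finite) space
of topologies and never optimizes or samples continuous parameters. On
three taxa, finding the optimal species tree takes exactly three
likelihood evaluations; on five taxa, 105.

### Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `tau` | truncation of the branch-length prior (coalescent units) | `Inf` | the untruncated exponential is the form used by all inference functions; finite `tau` is exposed for sensitivity analysis |
| `exp_rate` | rate of the exponential prior | 1 | one coalescent unit as prior mean branch length; the closed form generalizes the rate, and the default keeps the familiar $2/(j(j-1)+2)$ coefficients |
| `beta_shape` | Beta shape pair for $\gamma$ | (2, 2) | symmetric, mildly concentrated at 1/2, keeps closed factorial form; Beta(1,1) (uniform) is also conjugate and available |

## Numerical choices

* The coefficients $f(u,v,j)$ use the standard form with the product over
  $y = 0,\dots,j-1$ and the sum over $j = v,\dots,u$; this is forced by
  $p_{uu}(0)=1$ and row-normalization, and is validated in the test suite
  against a matrix-exponential of the pure-death chain (tolerance 1e-10 up
  to $u = 8$), never against a printed formula.
* $f(u,v,j)$ is computed in double precision. The alternating sum is
  ill-conditioned for large $u$, but history enumeration is capped at 10
  gene-tree leaves (so $u \le 10$), where doubles carry ample precision;
  the oracle agreement above is the evidence.
* All history products accumulate in log space; summation over histories
  uses log-sum-exp. Probabilities are clamped to $[0,1]$ against
  $-10^{-17}$-style roundoff.
* History enumeration is super-exponential; guards refuse more than 10
  leaves or 3 reticulations unless raised explicitly. This is the
  enumerative definition, not the faster dynamic program over ancestral
  configurations, which is out of scope.
* Integrated per-topology probabilities and per-topology deep-coalescence
  costs are memoized on canonical topology strings; multi-locus scores
  collapse repeated gene-tree topologies through a frequency table.

## Canonical forms and serialization

Trees and networks serialize with children ordered by smallest descendant
leaf label (ties broken by a structural signature), hybrid tags renumbered
in emission order, and each reticulation expanded at its first occurrence.
Isomorphic networks therefore serialize identically, which gives cheap
set-based deduplication during enumeration and search, and a canonical
dictionary key for memoization. The extended-Newick dialect is the
`#H`-tagged one with per-edge `:length:support:probability` fields; the
probability field on a reticulation parent edge is its inheritance
probability and designates that edge as the primary parent. The parser is
strict about degrees: a hybrid occurrence must have out-degree 1, so write
`((B,C))#H1`, not `(B,C)#H1`. Gene-tree inputs may carry branch lengths,
which are dropped: the model is defined on topologies, and one allele per
species is assumed (gene-tree leaf labels must equal network leaf labels).

## Search

`exhaustive_search` enumerates all rooted binary trees ($(2n-3)!!$ of
them) and, at `max_reticulations = 1`, every network obtained by
subdividing two edges and adding a reticulation edge (including a tail
above the root, so the class is closed under the reverse of displayed-tree
extraction), deduplicated canonically. Guards restrict exhaustive mode to
at most 6 taxa and 1 reticulation.

`hill_climb` starts from seeded random join trees and repeatedly takes the
best strictly-improving neighbor under a standard move set: rooted
nearest-neighbor interchange on tree edges, reticulation-edge addition,
deletion, and relocation (deletion followed by re-addition anywhere). The
exact published move repertoires of MDC-style network search tools are not
reproduced; this set is a documented substitute that connects the space at
the scales handled here. Ties are broken by lexicographically smallest
canonical string, so runs are deterministic given the seed; a tabu set
ensures no canonical topology is ever scored twice in a run. The MDC
criterion plugs into the same search machinery with score
$-\sum_i \mathrm{XL}(g_i)$, where `extra_lineages` minimizes
$\sum_b (v_b - 1)$ over histories (routing included); this reduces to the
classic tree MDC when there are no reticulations.

## The simulator

`simulate_dataset` implements the generative MSNC process directly (exact
exponential waiting times, uniform pair choice, independent routing at
reticulations) rather than shelling out to an external coalescent
simulator: this keeps the NCM regime exactly controllable and every run
seed-reproducible, with a per-locus parameter log. Two regimes define the
package's study conditions:

* **common**: one fixed $(\Lambda, \Gamma)$ for all loci; reference
  settings use branch lengths of 1 or 2 coalescent units and
  $\gamma = 0.5$;
* **ncm**: per-locus draws, lengths $\sim U(0, 2)$ or $U(0, 4)$ and
  $\gamma \sim U(0, 1)$.

The simulator emulates ILS and reticulation on known topologies with one
sampled allele per species. It does not emulate gene-tree estimation
error, linkage between loci, gene duplication/loss, migration, or multiple
alleles — so passing tests say the *method* matches its model, not that
real estimated gene trees satisfy that model.

## What the tests compute, at what sizes

The suite validates: parser round-trips over all enumerated 4-taxon
(and sampled 5-taxon) 1-reticulation networks; history enumeration against
a brute-force map-filter oracle on all 3- and 4-taxon tree pairs;
$p_{uv}$ against the matrix-exponential oracle and $p^\tau_{uv}$ against
adaptive quadrature; pmf normalization over all topologies for every
4-taxon species tree and a 3-taxon 1-reticulation network (tolerance
1e-8); the integrated gene-tree probability against direct quadrature of
pmf×priors (1D for the 3-taxon tree; nested 3D over the two root edges and
$\gamma$ for the reticulate case, tolerance 1e-6); simulator topology
frequencies at $10^5$ loci (3 binomial SE) and NCM-mode frequencies
against the parameter-averaged pmf; convergence of exhaustive NCM
inference on a 4-taxon tree with unit internal branches at 10/100/500 loci
(10 replicates each); and a fixed 4-taxon locus multiset on which the MDC
optimum (cost 4, all others &ge; 5) is disjoint from the two tied NCM
optima. These sizes were chosen as the smallest instances at which each
property is non-trivial.

## Open design decisions taken

* **Indistinguishability pairs.** Two 1-reticulation networks on
  {A,B,C,D} that both display exactly `((A,(B,C)),D)` and
  `(A,((B,C),D))` are constructed explicitly (reticulation into the
  `(B,C)` clade from both sides, versus a reticulation edge from above
  `(B,C)` into the `D` pendant). Search on data simulated from one of
  them may legitimately return either; results are therefore scored by
  displayed-tree set, not by isomorphism.
* **Network distance.** Reported comparisons use the normalized symmetric
  difference of hardwired-cluster multisets — a deliberate surrogate for
  reduction-based metrics, sufficient to score exact recovery
  (distance 0), which is all the reproduction experiments need.
* **Number of reticulations.** Neither criterion can select it; searches
  take `max_reticulations` as an input, mirroring standard practice of
  setting it to the assumed true number.

## Known limitations

One allele per species; rooted binary gene trees only; enumeration-based
likelihood (super-exponential in leaves and reticulations — fine through 6
taxa / 3 reticulations, the scales targeted here); no model selection for
reticulation count; hill-climbing is a local search and, like any greedy
ascent, inherits its usual caveats despite restarts and tabu.
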
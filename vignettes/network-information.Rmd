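---
title: "Information-theoretic characterisation and comparison of interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic characterisation and comparison of interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Protein–protein interaction networks (PPINs) produced by different detection
techniques (yeast two-hybrid, affinity-purification mass spectrometry) and by
different laboratories disagree substantially, and their most popular summary
— the degree distribution — is too coarse to say how. `ppinet` implements a
macroscopic characterisation of an undirected simple graph built from two
functions:

* the degree distribution $p(k)$, the fraction of nodes with $k$ partners,
  including the $k=0$ bin, with mean degree
  $\bar{k} = \sum_k k\,p(k) = 2E/N$;
* the normalised degree–degree correlation (DDC) kernel
  $$W(k,k') = \frac{\Pi(k,k')\,\bar{k}^2}{k\,p(k)\,k'\,p(k')},$$
  where $\Pi(k,k')$ is the probability that a uniformly drawn interaction,
  read in a uniform orientation, joins nodes of degrees $k$ and $k'$.
  $W \equiv 1$ signals the absence of degree correlations beyond those forced
  by $p(k)$ itself; $W(1,35) \gg 1$, for instance, is the hub–leaf enrichment
  typical of bait–prey protocols.

Everything else in the package is built from $(p, W, \bar{k})$: the
assortativity, two complexity measures, a distance between networks, and the
degree-preserving null models that calibrate all of them.

## Assortativity

The assortativity is the Pearson correlation of the degree pair at the two
ends of a uniformly drawn edge, computed under $\Pi$. Because
$\Pi(k,k') = W(k,k')\,k p(k)\,k' p(k')/\bar{k}^2$, the same number can be
computed from $(p, W)$; `net_assortativity()` exposes both routes and the
test suite holds them to $10^{-10}$ of each other. For a regular graph the
edge-end degree variance vanishes and the coefficient is reported as `NA`
("undefined"), never silently as 0.

## Complexity

The information-theoretic complexity per node measures how much information
is needed to single out the network's macroscopic structure within the
ensemble of random graphs of the same size and mean degree. It has two
non-negative parts:

* **degree complexity** $\sum_k p(k)\log[p(k)/\pi_{\bar k}(k)]$, the
  Kullback–Leibler divergence of $p$ from the Poisson law
  $\pi_{\bar k}(k) = e^{-\bar k}\bar k^k/k!$ with the same mean degree;
* **wiring complexity**
  $\tfrac{\bar k}{2}\sum_{kk'}\Pi(k,k')\log W(k,k')$, which is
  $\tfrac{\bar k}{2}$ times the Kullback–Leibler divergence of $\Pi$ from
  its degree-uncorrelated counterpart, and is exactly zero for
  degree-matched uncorrelated graphs.

Both are reported per node (in nats) and per link (per node divided by
$\bar k/2$); the per-link normalisation removes the trivial dependence on
the average degree, which matters when comparing sparse Y2H maps with
denser AP–MS maps. The per-link convention used here is exactly
per-node $\div\,(\bar k/2)$, the number of links per node; all per-link
comparisons in the package are internally consistent under this convention.

## The network distance

The distance between networks A and B is the symmetrised Kullback–Leibler
divergence, per node, between the maximum-entropy random-graph ensembles
pinned to each network's $(p, W, \bar k)$:

$$
D(A,B) = \tfrac12\sum_k\big[p_A(k)-p_B(k)\big]\log\frac{p_A(k)}{p_B(k)}
 \;-\;\tfrac14(\bar k_A-\bar k_B)\log\frac{\bar k_A}{\bar k_B}
 \;+\;\tfrac14\,\bar k_A\!\sum_{kk'}\Pi_A\log\frac{W_A}{W_B}
 \;+\;\tfrac14\,\bar k_B\!\sum_{kk'}\Pi_B\log\frac{W_B}{W_A}.
$$

Dropping the two $W$ terms gives the simplified, *degree-only* distance,
which involves only the two degree distributions; it is identically zero
between a network and any degree-preserving rewiring of it. Two internal
consistency properties anchor the formula and are enforced by tests: the
directional (unsymmetrised) divergence of a network from the uncorrelated
ensemble with its own mean degree reproduces the complexity above exactly,
and the distance obeys the axioms $D(A,A)=0$, $D(A,B)=D(B,A)$, $D \ge 0$.
The overall factor ($\tfrac12$, the Jeffreys convention for a symmetrised
divergence) is a scale convention; only relative distances matter for
clustering. Values are reported in nats.

## Smoothing, grids and degenerate cases

Finite networks leave zeros in $p$ and $\Pi$ that are sampling artefacts,
and a zero on one side of a log-ratio makes the distance infinite. Before a
distance is evaluated, both characterisations are therefore smoothed with a
discrete Gaussian kernel $\exp[-(k-k'')^2/2\sigma^2]$ along each degree
axis, on a grid shared by both networks (0 up to the larger maximum degree);
the kernel weights are renormalised where the window is clipped at the grid
boundaries, so each law's total mass is conserved exactly, and the smoothed
laws are strictly positive on the whole grid. The default width is
$\sigma = 1$ degree unit — weak enough to leave well-populated bins
essentially unchanged, wide enough to fill single-bin gaps; it is a tunable
argument everywhere. Smoothing is *mandatory* for distances (`sigma > 0`
enforced), while complexities may be computed exactly with the
$0\log 0 = 0$ convention.

After smoothing, the kernel $W$ is re-formed from the smoothed joint law and
its own marginals (not from the separately smoothed $p$): this keeps the
edge-end-weighted average of $W$ at exactly 1 and makes the wiring
part of the distance between degree-matched networks a proper symmetrised
divergence of the two joint laws, hence non-negative.

Other conventions: degrees $k=0$ contribute to $p$ and $\bar k$ but never to
$\Pi$ or $W$ ($W$ is defined for $k,k' \ge 1$ only). Degree pairs outside
the support of the edge-end marginal are *no data* and stored as `NA`;
in-support pairs with no observed edges are true zeros (suppression). For
heat-map rendering (`plot_ddc()`) the degree axes are truncated at
`kmax = 35` by default, beyond which typical interactomes no longer populate
bins densely enough for $W$ to be read as a clean probability-ratio
estimator; the truncation is a display/analysis option, not part of any
definition, and smoothing operates on the truncated range used for a given
computation.

## Null models

The null model of a network is a graph drawn **uniformly** from all simple
graphs with the same labelled degree sequence. Naive edge-swapping with
unconditional acceptance samples this space non-uniformly. `ppinet`'s
sampler proposes a swap uniformly from a state-independent candidate set
(ordered pairs of distinct edges × two re-pairings) and, in the default
`hold_counting` mode, treats proposals that would create a self-loop or a
duplicate edge as executed "stay" moves. The candidate-set size depends only
on $E$, which is invariant, so the chain is symmetric and its stationary
law is uniform. The alternative `mobility_ratio` mode accepts an executable
move with probability $\min(1, n(c)/n(c'))$, with $n(\cdot)$ the number of
executable swaps in a state; it targets the same uniform law at
$O(E^2)$ cost per step and serves as a cross-check on small graphs. Both
modes pass exhaustive-enumeration uniformity tests on matching spaces with
3, 15 and 105 states.

Equilibration uses the accepted-moves criterion: the chain runs until the
number of accepted (edge-changing) moves reaches 100 per link by default,
and logs a trace of assortativity and of the normalised Hamming distance to
the original so the user can verify the plateau and extend runs if needed.

The normalised Hamming distance implemented is
$\Delta = \sum_{i<j}|c_{ij}-c'_{ij}|/(E+E')$: zero for identical networks,
one for edge-disjoint ones. Two *independent* degree-matched sparse graphs
overlap by chance on $\approx \sum_{i<j}(k_ik_j/2E)^2$ edges, so their
expected $\Delta$ sits slightly below 1 at finite $N$;
`expected_hamming_independent()` computes this finite-size expectation from
the degree sequence, and the test suite compares equilibrated
randomisations against it rather than against the idealised limit value 1.

## Synthetic study networks

All tests and examples run on generated graphs (`generate_network()`):
Erdős–Rényi graphs at a target mean degree; uniform configuration-model
graphs (Havel–Hakimi realisation mixed by the unbiased sampler, after an
Erdős–Gallai graphicality check); toy graphs (star, cycle, path, matching,
regular); and *planted-correlation* families — a configuration start driven
by biased degree-preserving swaps until the assortativity reaches a target
$\pm r$ within a tolerance band (0.02 by default), exploiting the fact that
assortativity is affine in $\sum_{(ij)\in E} k_ik_j$ at fixed degrees. The
generators emulate the *statistical* structure real interactomes show
(Poissonian-to-broad degrees, hub–leaf disassortativity); they do not
emulate protocol-specific sampling biases (bait selection, spoke-model
expansion of complexes), so passing tests demonstrate correctness of the
estimators and samplers, not fidelity of any biological conclusion.

Study conditions used by the heavier checks, chosen once as representative
of curated interactome scales: null-model endpoint runs use Erdős–Rényi
graphs with $N = 2000$, $\bar k = 5$, 10 seeds; finite-size decay of
null-model wiring complexity is measured at $N \in \{500, 2000, 8000\}$ at
$\bar k = 5$; the sub-sampling experiment removes 10–90% of nodes in 10%
steps, 10 repeats per fraction, from a high-complexity exemplar with
planted disassortativity $r \approx -0.6$ at $N = 5000$, $\bar k = 6$
(wiring complexity $\approx 0.7$ nats/node, of the order of the most
strongly correlated real interactomes) against an equal-size Erdős–Rényi
graph. The two curves use common random removal sets (paired seeds), a
variance-reduction choice that sharpens the comparison of means at the
near-empty high-removal fractions. An *assortative* planted graph is
deliberately not used as the high-complexity exemplar: its hub core makes
sub-samples structurally similar to the original and the sensitivity
ordering inverts.

## Clustering and sub-sampling

`distance_matrix()` evaluates all pairwise distances on one common degree
grid and `cluster_networks()` feeds them to `hclust` with the `average`
agglomeration method; `export_newick()` writes the dendrogram as a Newick
tree (via `ape`) for comparison against external reference trees.
`subsample_curve()` removes $\lfloor fN \rfloor$ uniformly chosen nodes,
keeps the induced subgraph *including* newly isolated nodes (they honestly
change $p(0)$ and $\bar k$), and reports the mean ± sd distance to the
original per fraction; repeats whose subsample retains no edges are skipped
and counted.

## Known limitations

* The distance presumes both networks carry at least one edge, and its value
  depends (weakly, through smoothing) on the shared grid extent.
* At very high removal fractions or very small $E$, $W$ estimates are
  noise-dominated; distances between such fragments mostly reflect degree
  shrinkage plus estimator noise, and comparisons there need paired designs
  and/or many repeats.
* The planted-correlation generator reaches $|r|$ up to roughly 0.6 for
  Poissonian degrees at $\bar k \approx 6$; stronger targets are reported
  with the achieved value and a warning.
* Null models constrain degrees only; ensembles constraining degrees *and*
  degree correlations jointly are out of scope.
* Identifier curation (accession mapping, confidence filtering, complex
  expansion) is out of scope: readers treat identifiers verbatim.
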
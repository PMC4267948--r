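---
title: "Error-corrected maximum likelihood phylogeny inference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-corrected maximum likelihood phylogeny inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloerr)
```

## The problem

DNA sequences carry base-calling errors. Classical maximum likelihood (ML)
phylogeny inference treats every observed base as certain, so miscalls are
absorbed into the only free quantities available — the branch lengths —
inflating them, and, when errors are abundant, distorting the topology.
`phyloerr` implements ML tree inference in which a *declared* per-base
miscall rate $\varepsilon$ enters the likelihood directly, together with
the simulation machinery needed to study what happens when the declared
rate differs from the true one.

## The error model in the tip likelihoods

Under the standard pruning (peeling) algorithm, each alignment column
contributes a likelihood computed from conditional vectors propagated from
the tips to the root. The vector stored at a tip holds
$\Pr(\text{observation} \mid \text{true base} = x)$ for
$x \in \{A, C, G, T\}$ — probabilities *of the observation*, which need not
sum to one.

We assume a base is miscalled as each of the three other bases with
probability $\varepsilon/3$ (total miscall probability $\varepsilon$),
independently across sites and sequences, and that IUPAC ambiguity codes
are produced downstream of the error process from specific (possibly
wrong) calls. For an observed symbol with resolution set $S$, $|S| = k$:

$$
\Pr(\text{obs} \mid x) =
\begin{cases}
1 - \varepsilon + (k - 1)\varepsilon/3 & x \in S\\[2pt]
k\,\varepsilon/3 & x \notin S
\end{cases}
$$

So an observed `A` gives $(1-\varepsilon, \varepsilon/3, \varepsilon/3,
\varepsilon/3)$, an observed `M` ("A or C") gives $(1-2\varepsilon/3,
1-2\varepsilon/3, 2\varepsilon/3, 2\varepsilon/3)$, and `N`, `-`, `?` give
$(1,1,1,1)$ for every $\varepsilon$. At $\varepsilon = 0$ every code
reduces to the classical 0/1 indicator vector. The domain is capped at
$\varepsilon < 0.75$: at $0.75$ a call is uniformly random and the model
carries no information (beyond it, the model inverts).

```{r tipvec}
tip_vector("M", 0.01)
```

The declared $\varepsilon$ is a fixed input, never estimated; it may be
global or per sequence (`error_spec(per_taxon = ...)`), reflecting data
sets that mix platforms or read depths.

## Substitution model

Both simulation and inference use the Kimura 2-parameter model with
uniform base frequencies, parameterized by the transition/transversion
ratio $R = \alpha/(2\beta)$ (total transition rate over total transversion
rate; default $R = 2$). Rates are normalized so $\alpha + 2\beta = 1$,
making branch lengths expected substitutions per site. Using one model on
both sides isolates the effect of the error correction from model
misspecification — classical ML tools often default to richer models
(e.g. F84 with empirical frequencies), but a matched pair is the cleaner
experiment, and the data are simulated under K2P.

Transition probabilities use the closed form; the suite cross-checks them
against a matrix exponential of the generator, and the pruning likelihood
against exhaustive summation over internal-node states.

## Optimization

Branch lengths are optimized one at a time by bounded Brent search on the
log-likelihood, swept until the per-sweep gain drops below `tol_lnl`.
Three numerical choices matter:

* **Log-scale search.** Lengths live in `[bl_min, bl_max]` = `[1e-8, 100]`
  and optima range over several orders of magnitude; searching
  $\log b$ gives uniform relative resolution and behaves well near
  `bl_min`, where the error model can flatten the surface until the
  curvature nearly vanishes (the reason we avoid Newton steps).
* **Cached partials.** For a focal branch, conditionals above and below it
  are cached so the 1-D objective costs $O(\text{patterns})$ per
  evaluation rather than a full tree traversal.
* **Monotonicity.** A proposed length (or height, or rearrangement) is
  accepted only if it improves the log-likelihood, so the trajectory is
  non-decreasing by construction.

Clock-mode inference optimizes internal node *heights* instead, each
bounded between its highest child and its parent, and returns exactly
ultrametric trees. Topology search is seeded random-order stepwise
addition (every branch tried for each added taxon, best kept) followed by
nearest-neighbor-interchange sweeps until no move gains more than
`tol_lnl`; ties are broken by first encounter, so results are
deterministic given the seed. Conditional vectors are renormalized
per-node with accumulated logs, which keeps 20-taxon, 20,000-site
computations stable in double precision.

The two-taxon initializer `ml_pairwise_distance()` profiles the
transition/transversion ratio out, so at $\varepsilon = 0$ it reduces
exactly to the classical closed-form K2P distance
$-\tfrac12\log(1-2P-Q) - \tfrac14\log(1-2Q)$.

## The simulation laboratory

`simulate_yule_tree(n_taxa, t)` draws clocklike pure-birth trees: starting
from two lineages, each lineage splits at rate $1/t$, and after the target
tip count is reached a final exponential interval is appended so terminal
branches are non-degenerate. The documented calibration is that the
interval while $k$ lineages exist is $\mathrm{Exp}(k/t)$ — in particular
the rootmost interval has mean $t/2$ — giving an expected total tree
length of $(n-1)\,t$. This emulates between-species phylogenies (a
branching process, deliberately not a coalescent); it has no extinction,
no rate variation among lineages and no indels.

`evolve_alignment()` drops a uniform root sequence and mutates each site
along each branch with the K2P transition matrix; `inject_errors()` then
miscalls each cell with its taxon's $\varepsilon$, uniformly over the
three other bases. Tree shape, evolution and error injection take
independent seeds, so one base data set can be re-used across error
realizations — the paired design the experiment harness relies on.

`bernoulli_snp_alignment()` is a direct generator of alignments with a
known mutation-polymorphism density $m$ (each site is, with probability
$m$, a singleton SNP). Composing it with error injection reproduces
published segregating-site densities via
$\Pr(\text{segregating}) \approx 1 - (1-m)(1-\varepsilon)^{n}$; the
acceptance script measures these cells by simulation, not by this formula.
We do not target the *mutation-only* densities of tree-based simulations:
the original tree generator is documented only through its rootmost
interval property, and a plain Yule process calibrated to that property
yields systematically lower SNP densities than the published mutation-only
row, so those cells would test the undocumented generator rather than the
error model. The Bernoulli fixtures decouple that ambiguity.

## Tree comparison

`rf_distance()` is the Robinson–Foulds symmetric difference over
non-trivial bipartitions (even; at most $2(n-3)$ for binary trees; an
increase of 2 is one misplaced branch). `rfl_distance()` sums absolute
branch-length differences over the union of splits, *including pendant
edges*, counting absent splits as length zero. Published work does not
always state whether pendant edges are included or whether differences are
absolute or squared; we chose absolute differences with pendants because
pendant lengths carry most of the error-inflation signal, and isolated the
choice behind one function so a squared (branch-score) variant is easy to
compare. Rooted (clock) inferences are unrooted before either metric, so
clock and non-clock output are scored identically; splits are kept for
zero-length branches (topology comes from tree shape, not length
thresholding).

## The experiment harness

`run_condition()` sweeps a grid of declared error rates over replicated
simulated data sets, recording mean RF, mean RFL and the mean
inferred/true total-length ratio per grid point, plus the mean SNP density
of the observed data. Replicate seeds derive from the master seed by fixed
arithmetic and are shared across the grid, so all grid points are paired.

The default checks in this package run at desk scale — 10–20 replicates of
10 taxa and 2,000 sites rather than 100 replicates of 20 taxa and 20,000
sites — which preserves the qualitative structure (correction lowers RFL;
the length ratio falls monotonically in declared error and crosses 1 near
the true rate) at a few minutes per condition. Full-scale settings are a
`simulation_config()` call away.

## Limitations

* Errors are independent across sites; clustered (assembly-type) errors
  are out of scope, as are quality-score-derived site-specific rates.
* The search is stepwise addition + NNI; no SPR/TBR, no bootstrap.
* DNA only (RNA via U→T); amino-acid and codon alphabets are not handled.
* $\varepsilon$ is never estimated from the data; Bayesian treatment of
  $\varepsilon$ as a parameter is out of scope.
* Simulated trees have no extinction and a strict clock; passing tests on
  them says nothing about, e.g., rate heterogeneity across lineages.
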
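---
title: "Phylogeny-aware Potts model inference: model, assumptions, choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-aware Potts model inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phylopotts)
```

## The model and what it corrects

A Potts model over aligned sequences of length $L$ on a $q$-letter alphabet
assigns energies
$H(A) = -\sum_{i<j} J_{ij}(A_i, A_j) - \sum_i h_i(A_i)$ and probabilities
$P(A) \propto e^{-H(A)}$. DCA estimates $(J, h)$ from an MSA under an i.i.d.
assumption that phylogeny violates: rows share ancestry, so sub-clades
over-represent regions of sequence space and both the site frequencies
$f_i$ and the connected correlations $c_{ij} = f_{ij} - f_i f_j$ are biased.

This package estimates the *stationary* statistics $\omega$ of the
evolutionary process instead of the raw $f$, given a rooted tree with branch
lengths, and feeds them back into standard plmDCA. The exact likelihood of
the parameters given leaves and tree requires summing over all internal-node
sequences — $q^L$ states per node — so two factorized approximations are
used, each with a closed-form propagator whose stationary law is the
quantity being estimated:

* **Independent sites.** Along a branch of length $\Delta t$, a site keeps
  its state with probability $e^{-\mu\Delta t}$ and otherwise re-draws from
  $\omega_i$. This is the classical one-parameter substitution model with an
  arbitrary stationary profile; it is reversible, stationary and forms a
  semigroup (all three are tested to $10^{-10}$).
* **Independent pairs.** A pair keeps both states w.p. $e^{-2\mu\Delta t}$;
  exactly one site mutates w.p. $e^{-\mu\Delta t}(1-e^{-\mu\Delta t})$ and
  re-draws from the *conditional* $\omega_{j|i}$ (this is where epistasis
  enters); both mutate w.p. $(1-e^{-\mu\Delta t})^2$ and re-draw jointly from
  $\omega_{ij}$. Note that when $\omega_{ij}$ is a product table the pair
  propagator is exactly the tensor product of two site propagators — the
  pair model strictly generalizes the site model.

Likelihoods are computed by Felsenstein pruning (post-order elimination of
internal nodes, per-node rescaling against underflow, multifurcations
supported), and maximized over $\omega$ by a stochastic hill climb, because
the likelihood gradient in $\omega$ is impractical and concavity is unknown.

Pairs sharing a site cannot truly evolve independently: unconstrained
per-pair optima give inconsistent marginals for the shared site (the
diagnostic mode of `correct_all_pairs(..., constrain = FALSE)` measures
this). The method therefore pins every pair table's marginals to the
site-stage profiles via the reparameterization
$\omega_{ij} \propto \exp(J(A,B) + \tilde h_i(A) + \tilde h_j(B))$:
moves act on $J$, and the compensatory fields are re-fit after every move.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `mu` | fitted (`estimate_mu`) | substitutions per site per clock unit | The distance–time curve $d(\Delta t) = d_\infty(1-e^{-\mu\Delta t})$ identifies it from data; on coupled models the effective rate is below the simulator's rate because Gibbs dynamics slow down, so fitting is preferred over plugging in the nominal value. |
| `optimizer_schedule(n_iter)` | 2000 | moves | Hill-climb budget per site/pair; likelihood plateaus well before this at desk scales. |
| `mag0`, `mag1` | 0.3 → 0.003 | simplex / coupling units | Geometric cooling of the move size: large early displacement, fine final adjustment. |
| `p_global` | 0.3 | fraction | Mix of global (all-coordinate) vs local (one-coordinate) moves. |
| simplex floor | `1e-6` | probability | Keeps $\omega$ strictly interior so observed leaf states never get zero likelihood. |
| `j_bound` | 8 | coupling units | Keeps the IPF scaling well conditioned ($e^{8}\approx 3000$). |
| IPF tolerance | `1e-10` | max marginal error | Stopping rule for the compensatory-field fit; pinned marginals are exact to this tolerance at every accepted step. |
| `anneal_schedule` | `200 M L` moves, $\beta: 10 \to 10^4$, 20 stages | — | Chosen so the $2^{12}$-leaf toy run finishes in minutes; the best-seen configuration is returned because finite-$\beta$ Metropolis can end uphill. |
| `lambda_J`, `lambda_h` | 0.01 | L2 penalty on the weight-normalized pseudo-likelihood | The plmDCA literature convention; the 2-site contingency-table oracle shows the induced shrinkage is well under the 5% recovery tolerance. |
| reweighting threshold | 0.8 | sequence identity | The classical DCA baseline arm, for comparison only. |

Sampling defaults: equilibrium draws use one Gibbs chain with 1000 full-sweep
burn-in and $L$-sweep thinning (total-variation error against exact
enumeration at $L=3, q=2$ is below 0.01 at $M = 10^5$); the root sequence of
every tree simulation is drawn the same way.

## The synthetic world and what a green test establishes

The generator reproduces the validation protocol of the underlying method:
a sparse ferromagnetic toy model ($L = 25$, $q = 4$; couplings
$J_{ij} = s_{ij} x_{ij} \delta_{ab}$ with $s_{ij}\sim\text{Bern}(c/L)$,
$c = 3$, $x \sim N(0.8, 0.2)$; fields $h_i(a) \sim N(0, 0.6)$ i.i.d. per
$(i,a)$), evolved down balanced binary clock trees of $2^K$ leaves with
$\text{Poisson}(\mu L \Delta t)$ Gibbs mutation events per branch, at
$\mu L \Delta t \in \{3, 5, \infty\}$ and $\Delta t = 0.3$. Note the exact
mean degree of the coupling graph is $c(L-1)/L = 2.88$; "$c$ neighbors" is
the large-$L$ reading.

This world has in common with real protein data the two features that matter
for the method — hierarchical correlation of rows and a sparse pairwise
energy landscape — but it is *not* real data: the tree is exactly known and
clock-like, the mutation process matches the assumed propagator family, the
alphabet is small, there are no gaps or indels, and selection is stationary.
Green tests therefore establish internal correctness (the estimators recover
what the stated world defines) and the method's comparative value *in that
world*; they do not establish performance on protein families, where the
paper-level evidence is itself mixed and tree inference error dominates.

Two ambiguities the sources leave open, decided here once:

* Whether the toy fields are drawn i.i.d. per $(i, a)$ or per site: notation
  is ambiguous; i.i.d. per entry is the default (`field_mode = "per_entry"`),
  the alternative is a flag.
* The pair-recovery experiment (a 2-site process on a $K = 10$ tree) needs a
  per-branch divergence; $\mu\Delta t = 0.3$ is used. At much smaller values
  the leaves are so correlated that the maximum-likelihood table itself
  scatters by more than the test's total-variation budget — a property of
  the data regime, not of the optimizer.

## Numerical choices

* Pruning partials are rescaled per node by their maximum, accumulating the
  log; leaf messages use the one-hot shortcut and the pair message is
  contracted in $O(q^2)$ via the propagator's low-rank structure.
* Optimizer acceptance is *strictly greater* likelihood; ties are rejected.
  Simplex moves are additive Gaussian, clipped at the floor, renormalized.
* $J$ is zero-centered after every accepted pair move — a pure gauge choice
  absorbed by the compensatory fields, kept for bit-reproducibility.
* The annealer tracks $\|C - C^{\text{target}}\|_F$ over all $i<j$ blocks of
  connected correlations (site-diagonal blocks excluded — within-column swaps
  leave $f_i$ fixed, so diagonal blocks would only add a constant offset) and
  maintains the squared distance incrementally; an R reference implementation
  (`incremental_covariance_update`) is tested against recomputation.
* Pseudo-likelihood is normalized by total weight, optimized per site by
  L-BFGS-B with analytic gradients, symmetrized by averaging, and reported in
  zero-sum gauge. Degenerate inputs (zero-variance mutant vectors, empty
  alignments, zero marginals) raise conditions rather than propagate NaN.
* All randomness — including inside C++ kernels — flows through R's RNG, so a
  single `set.seed()` reproduces any run bit-exactly.

## Design choices where the design was open

* The compensatory fields are computed by alternating row/column scaling
  (Sinkhorn / iterative proportional fitting). The sources say only that the
  fields are "re-estimated"; IPF converges to the unique table with the given
  odds ratios and marginals, which is exactly the reparameterized family.
* Pair optimization starts from $J = 0$ (the independence table pinned to the
  corrected marginals), so the accepted-move trace starts at the natural
  baseline and improvement over independence is guaranteed by construction.
* The KL metric uses the symmetrized form estimated from two Gibbs samples
  (default $10^4$ sequences, $L$-sweep thinning; the repetition harness uses
  4000, where the MC standard error ~0.1 is far below the inter-arm gaps).
* Statistics comparisons flatten *all* table entries (gap/reference states
  included); a `drop_major` mode exists because the alternative convention is
  defensible.
* Contact ranking uses Frobenius norms in zero-sum gauge without average
  product correction by default (APC is available behind a flag); the toy
  graph has no chain structure, so no minimum separation filter is applied —
  protein mode would default to $|i-j| \ge 5$.

## Known limitations

* The correction assumes the tree (topology and branch lengths) is correct
  and clock-like in expectation; errors in an inferred tree propagate
  directly into the likelihoods.
* The independent-pair approximation repairs marginal consistency but not
  global coherence: the corrected covariance is generally not positive
  semidefinite, which is why the mean-field (inverse-covariance) route is
  excluded by design and the annealed-alignment route is used instead. The
  combined site-only statistics (`combine_site_correction`) routinely
  produce entries outside $[0,1]$; they are counted and flagged, never
  clipped.
* Runtime of the pair stage is $O(L^2)$ pruning problems; for protein-scale
  $L$ and $q = 21$ this is the binding cost.
* The pairwise stage's advantage over the site-only route grows with the
  number of leaves: at a few hundred leaves the connected-correlation
  recovery margin over raw counting is small, so the two corrected models can
  tie on the KL metric; with $2^{10}$ leaves and more the pairwise route is
  consistently closer to the generating model. Small alignments mainly
  benefit from the site correction.
* The full-sequence tree likelihood exists only as a brute-force test oracle
  on tiny instances under a factorized propagator; the general case is out of
  scope by design.
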
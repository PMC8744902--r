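---
title: "Google-matrix analysis of signed interaction networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Google-matrix analysis of signed interaction networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regomax)
```

## The model

A curated protein–protein interaction database is a directed network: a
link $j \to i$ records that protein $j$ acts on protein $i$, with a sign
(activation, inhibition) or no sign (neutral/unknown). This package
analyzes such networks with the Markov-chain machinery originally built
for the web graph.

**Google matrix and PageRank.** From the binary adjacency $A$ (signs and
multiplicities ignored), the column-stochastic matrix $S$ divides each
nonzero column by its sum; dangling columns (nodes with no outgoing
links) become the uniform column $1/N$. The Google matrix is

$$G = \alpha S + (1 - \alpha) \tfrac{1}{N} \mathbf{1}\mathbf{1}^T,$$

with damping $\alpha = 0.85$, the conventional value, as default. Its
stationary vector $GP = P$ is the PageRank: the probability of finding a
random surfer at each node, large for influential nodes with many
important incoming links. The CheiRank $P^*$ is the PageRank of the
link-inverted network and measures outgoing connectivity. Rank indices
$K, K^*$ order nodes by decreasing probability. $G$ is never formed
densely: `google_matrix()` stores $(S, \alpha)$ and applies the
teleportation and dangling corrections analytically, so all iterations
are sparse.

**Reduced Google matrix (REGOMAX).** For a subset of $N_r \ll N$ nodes,
writing $G$ in block form over the subset ($r$) and the complementary
scattering network ($s$), the reduced matrix

$$G_R = G_{rr} + G_{rs}(1 - G_{ss})^{-1}G_{sr}$$

is the effective column-stochastic matrix on the subset: direct
transitions plus *every* indirect pathway through the rest of the
network (a stochastic-complement/Schur construction). Its PageRank
equals the global PageRank restricted to the subset and renormalized,
which the test suite checks explicitly. $G_R$ splits into three parts,
$G_R = G_{rr} + G_{pr} + G_{qr}$: the direct block; a rank-1 background
built from the leading right/left eigenvectors $\psi_R, \psi_L$ of
$G_{ss}$ (eigenvalue $\lambda_c < 1$ because probability escapes from
the scattering block into the subset); and the deviations $G_{qr}$,
which carry the informative indirect pathways and may contain negative
entries. Component weights are element sums divided by $N_r$; $W_R = 1$
identically.

**Ising doubling of signed links.** To use the signs, every node is
split into an activated $(+)$ and inhibited $(-)$ copy and each link
becomes a $2 \times 2$ block on (target label, source label):

$$\sigma^+ = \begin{pmatrix}1&1\\0&0\end{pmatrix},\quad
  \sigma^- = \begin{pmatrix}0&0\\1&1\end{pmatrix},\quad
  \sigma^0 = \tfrac12\begin{pmatrix}1&1\\1&1\end{pmatrix},$$

with multiplicities adding blocks. Both source labels emit the same
column, so collapsing the doubled chain reproduces the simple chain:
for multiplicity-free networks the split PageRank satisfies
$P(j) = P^+(j) + P^-(j)$ *exactly*, and the suite verifies it to
$10^{-13}$ with power iterations converged to $10^{-15}$. The
magnetization $M(j) = (P^+ - P^-)/(P^+ + P^-) \in [-1, 1]$ summarizes
whether a node is reached predominantly through activating or
inhibiting paths. With multi-edges the simple network stays binary
while the doubled one is weighted, so the identity holds only
approximately; the generator therefore defaults to multiplicity-free
output.

**PageRank sensitivity.** The influence of one transition $b \to a$ of
$G_R$ on the stationary probabilities is the logarithmic derivative

$$D_{(b \to a)}(j) = \frac{1}{P_r(j)}\,
  \frac{dP_r^\varepsilon(j)}{d\varepsilon}\Big|_{\varepsilon = 0},$$

where the perturbed matrix multiplies element $(a, b)$ by
$(1+\varepsilon)$ and renormalizes column $b$. The derivative is exact,
not a finite difference: the derivative of the perturbed matrix has a
single nonzero column $E_{\cdot b} = G_R(a,b)\,(e_a - G_{R,\cdot b})$,
and $P'$ solves $(I - G_R)P' = E P_r$ on the zero-sum subspace. We
deflate the unit eigenvalue with the rank-1 term $P_r \mathbf{1}^T$,
which pins $\mathbf{1}^T P' = 0$ and makes the system nonsingular; one
LU factorization then yields the whole sensitivity matrix
$D_{ab} = D_{(b \to a)}(a)$ in closed form. For an exactly rank-1
reduced matrix (every column equal to $P_r$) the deflated matrix is the
identity and $D_{ab} = (1 - P_r(a))P_r(b)$ — the "background law" that
makes high-PageRank sources dominate aggregate sensitivities. Both the
closed form and agreement with central finite differences are part of
the test suite.

**External influencer (X-protein) selection.** Given an internal group
(seed proteins plus experimentally ranked up/down responders),
`select_x_proteins()` (i) enumerates every outside node with at least
one direct link into the top-5 up and top-5 down responders, (ii) forms
the intermediary subset of internals followed by candidates ordered by
global PageRank index, (iii) computes its reduced matrix and
sensitivity matrix, (iv) scores each candidate by the sum of its
sensitivities on the ten top responders, and (v) keeps the top
`n_select`, ordered by local PageRank. The 5/5/10 defaults are the
published procedure's; all three are parameters.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.85 | damping; rankings are stable over (0.5, 0.95) |
| PageRank `tol` | 1e-14 | L1 stopping rule; supports the 1e-13 doubling identity |
| `eig_tol` | 1e-14 | power-iteration tolerance for $\psi_R, \psi_L$ of $G_{ss}$ |
| `series_tol` | 1e-12 | max-norm truncation of the $G_{qr}$ spectral series (cap 10,000 terms) |
| `n_top_up`, `n_top_down`, `n_select` | 5, 5, 10 | selection procedure sizes |
| `branch`, `levels` | 4, 2 | diagram expansion width and depth |

## Numerical choices

* **Two REGOMAX routes.** `dense_solve` does one sparse LU of
  $I - \alpha S_{ss}$ and folds the teleportation-plus-dangling rank-1
  correction in with the Sherman–Morrison identity, so nothing of size
  $N_s \times N_s$ is ever densified; `spectral_series` sums
  $G_{rs}\,[\sum_l \bar G_{ss}^l]\,G_{sr}$ with
  $\bar G_{ss} = Q_c G_{ss} Q_c$, $Q_c = 1 - \psi_R\psi_L^T$. They are
  mutual cross-checks and agree elementwise to better than $10^{-10}$
  on every network in the suite; `dense_solve` is the default.
* **$G_{ss}$ columns are not renormalized** — the escape probability
  into the subset is exactly what makes $\lambda_c < 1$ and the series
  convergent.
* **Ties** in every ranking break by ascending node index (or ascending
  table position $K_g$ where a group table is in play); the underlying
  ordering in the literature is unspecified, so a fixed deterministic
  rule is used everywhere and makes runs byte-reproducible.
* **Degenerate inputs.** The full-subset reduction returns
  $G_R = G_{rr} = G$ with $G_{pr} = G_{qr} = 0$; single-node rank
  planes are rejected (the log-range is empty); edgeless networks are
  all-dangling and give uniform PageRank.
* **Orientation.** Matrix element $(i, j)$ is always the transition
  $j \to i$; friend expansion of node $n$ reads column $n$, follower
  expansion reads row $n$, and exported matrices are written
  row = target, column = source.
* **Diagram rules.** Link strength is the modulus of the matrix
  element (the signed value is kept as an edge attribute); links with
  both endpoints in the seed/external group are skipped; the
  U1/U2 (D1/D2) color comparison is a strict inequality, so exact ties
  fall to the second color — documented rather than guessed, since the
  tie case is unspecified in the source procedure.
* **Neutral links count** as links in the candidate enumeration by
  default (`count_neutral = TRUE`): the simple network underlying the
  reduction is unsigned. The flag exists because the alternative
  reading is defensible.

## The synthetic generator

Real curated interaction databases are commercial; the generator exists
so that every stage is testable. `generate_ppi_network()` emulates the
published coarse statistics — mean out-degree 7.3 and sign fractions
(65157, 49321, 177713)/292191 — with Poisson out-degrees truncated to
$[1, N-1]$ and target choice by linear preferential attachment on
in-degree (`attachment_exponent = 1`), which produces the heavy-tailed
in-degree profile that makes PageRank behave as on real databases. The
published material gives no degree law beyond the mean, so the
attachment model is a declared stand-in, not a claim about the real
topology. Each call runs one private RNG stream from its seed and
restores the global RNG state.

What passing tests on these networks do show: the algebraic contracts
(stochasticity, decomposition identities, the doubling identity, the
derivative's correctness, recovery of planted influencers). What they
do not show: anything about the real database's community structure,
motif content, or curation biases — reference values that depend on the
commercial network's content ship only as documentation fixtures
(`fibrosis_fixture()`), and the two fits on its printed influence table
are the only quantities reproduced from the publication itself.

`plant_influencers()` builds recovery instances: chosen external nodes
get `boost` new direct links into the top-response targets plus `boost`
incoming links (raising their PageRank). The suite requires the
selection to recover at least 2 of 3 planted nodes in its top 3 for at
least 8 of 10 seeds on 600-node backgrounds with `boost = 10`.

## Validation problem sizes

The suite exercises networks of 50–2000 nodes (5000 for sign-fraction
statistics), reductions of $N_r$ = 10–110, and 10-seed ensembles for the
stochastic properties; these sizes keep the full suite under ten
seconds while leaving every tolerance far from its bound (the two
REGOMAX routes, for instance, agree to ~$10^{-13}$ against the
$10^{-10}$ requirement).

## Known limitations

* The sensitivity solver is dense in $N_r$ ($O(N_r^3)$); it is meant
  for the few-hundred-node reductions the method targets, not for
  thousands.
* `dense_solve` factorizes an $N_s \times N_s$ sparse matrix; for
  networks far beyond $10^5$ nodes the `spectral_series` route is the
  practical one.
* The generator matches density and sign mix only; no attempt is made
  to reproduce reciprocity, clustering, or annotation-driven structure.
* Diagram export writes DOT/GraphML attributes (level, parent, color,
  stage, signed strength) but deliberately no layout geometry.

## A compact example

```{r example, eval = FALSE}
net <- generate_ppi_network(1000, seed = 1)
model <- google_matrix(net, alpha = 0.85)
pr <- pagerank(model)
rs <- reduced_google(model, sort(pr$order[1:20]), P = pr$P)
component_weights(rs)$W_R        # 1 by construction
sens <- sensitivity_matrix(rs)
mag <- ising_pagerank(ising_network(net))
max(abs(mag$P_sum - pr$P))       # doubling identity
```
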
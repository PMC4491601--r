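---
title: "Tropical aggregation and metric embedding of multiplex networks: methods"
author: "tropnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tropical aggregation and metric embedding of multiplex networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tropnet)
```

## The model

`tropnet` treats a group of weighted networks on one shared node set —
typically one functional connectome per subject, plus a structural
connectome on the same atlas — as objects of a single algebra, the
tropical semiring $L = (\mathbb{R}^+_0 \cup \{+\infty\}, \oplus =
\min, \otimes = +)$. Under this algebra the matrix product composes
path lengths, so the accumulated tropical powers of a distance matrix

$$N_{\text{embedded}} = N^* \oplus N^{*2} \oplus \dots \oplus N^{*r}$$

converge (at $r \le n-1$) to the all-pairs shortest-path distances: the
**metric closure**. Closure enforces the triangle inequality, i.e.
transitivity of the graph topology, and places every network in a
common metric space where entrywise comparison is meaningful.

Three representations are used:

* **proximity space** $w \in [0,1]$, larger = more connected, diagonal 1;
* **distance space** $d \in [0, \infty]$, smaller = closer, diagonal 0;
* the order-reversing isomorphisms between them, $d = 1/w - 1$
  (dialect `"reciprocal"`, the default) and $d = -\log w$ (dialect
  `"log"`). Both round-trip exactly and both send $w = 1 \mapsto d = 0$.

### Functional connectivity from time series

A functional edge is the zero-lag Pearson correlation of the two
standardized regional signals, Fisher-transformed,
$Z = \tfrac12 \ln\frac{1+r}{1-r}$. Under independence $Z \sim N(0,
1/(df-3))$; for autocorrelated series the nominal sample size $N$
overstates the information content, so the package corrects it per pair:

$$\frac{1}{df_{ij}} \approx \frac{1}{N} + \frac{2}{N} \sum_{\tau}
\frac{N-\tau}{N}\, r_{ii}(\tau)\, r_{jj}(\tau),$$

with $r_{xx}(\tau)$ the biased sample autocorrelation. The lag sum is
truncated at $\tau_{\max} = \lfloor N/5 \rfloor$ by default rather than
run to $N-1$: each additional lag of pure noise contributes variance
$\sim 1/N^2$ to the sum, so the full range accumulates a correction
noise of sd $\approx \sqrt{1/(3N)}$ — at $N = 1000$ about 3.7% of
$1/df$ — while realistic autocorrelation (an AR(1) with coefficient
0.9 decays below $10^{-9}$ by lag 200) is fully captured well inside
$N/5$. `maxLag = N - 1` restores the untruncated sum. Pairs whose
computed $1/df$ is nonpositive are clamped to just above $df = 3$ with
a warning, keeping the null variance positive; this is the
conservative direction (a huge null variance, nothing declared
significant by accident).

Significance gating is **not** applied by default when building a
proximity network: the normalization below consumes the full Z matrix,
and discarding edges before normalization is an analysis decision the
caller must opt into (`alpha =` in `buildFunctionalNetwork()`).

### Normalization

Raw weights (e.g. Fisher Z values) are mapped onto $[\epsilon,
1-\epsilon]$ by the unique affine function sending the off-diagonal
minimum to $\epsilon$ and maximum to $1-\epsilon$. Default $\epsilon =
0.01$. The margin prevents the extremes from degenerating (weight 1
merges two vertices under closure; weight 0 isolates them). MIN/MAX
are taken over off-diagonal entries only — the diagonal is a self-loop,
not an edge, and is forced to proximity 1 afterwards. Because a single
affine map is order-preserving, the network's topology is unchanged.

Normalization is applied **per network** by default; a `pooled` scope
(one range across all layers) is available when cross-subject weight
comparability matters more than per-subject contrast.

### Aggregation and per-layer contribution

Two group representatives are implemented:

* **algebraic**: entrywise $\oplus = \min$ over homologous distance
  edges, $N^* = N_1 \oplus \dots \oplus N_k$, then closure. When
  interlayer couplings are at proximity 1 (distance 0) — the multiplex
  case — this entrywise collapse is exactly equivalent to shortest
  paths on the full supra-adjacency tensor, so the $O((kn)^3)$ tensor
  walk is never materialized ($O(kn^2)$ instead).
* **average**: entrywise mean in proximity space, then one map to
  distance space and closure. A flag (`averageZ`) instead averages the
  raw Z matrices before a single normalization.

Contribution credit is assigned at the aggregation step: a layer is
credited for every finite aggregate edge it attains (ties shared,
tolerance $10^{-12}$), and layers with zero credited edges are flagged
as outliers. Credit via membership in realized shortest paths of the
closure was considered and rejected: tie-broken path enumeration is
underdetermined, so the same input can yield different path sets
depending on iteration order, which makes "contribution" ill-defined
at exactly the edges where it would be interesting.

The convergence parameter $r$ defaults to `"auto"` (repeated tropical
squaring with accumulation until an exact fixpoint, at most
$\lceil \log_2(n-1) \rceil + 1$ products); an integer $r$ accumulates
powers $1 \dots r$ and stops short of full transitivity, which is
occasionally useful to inspect bounded-hop structure.

### Comparison of two modalities

Embedded networks from different modalities differ in scale, so each
embedded edge distribution is z-scored — mean and sd estimated from
exactly the off-diagonal upper triangle, diagonal excluded — and the
comparison statistic is the difference grid $M = |z(A) - z(B)|$.

Each node's row of $M$ is its coordinate vector in the difference
space. The node's displacement from the origin is defined as the
root-mean-square of that row over its $n-1$ coordinates. The RMS (not
the plain Euclidean norm, which is available via
`normType = "euclidean"`) keeps displacement in the same SD units as
the z-scored edges, so the conventional threshold $s = 1$ reads
literally as "one standard deviation". Detection happens in the full
$(n-1)$-dimensional space; the 3D MDS projection is exploratory
visualization and never feeds detection. Classical (Torgerson) MDS is
used because it is deterministic — no seed, no majorization loop — and
exact on Euclidean inputs; its stress is reported as the normalized
residual $\sqrt{\sum (d - \hat d)^2 / \sum d^2}$. Closed distance
matrices are generally non-Euclidean, so some eigenvalues of the
doubly-centered matrix may be negative; only nonnegative eigenpairs are
kept and missing dimensions are padded with zeros. (For non-Euclidean
inputs stress is consequently not guaranteed monotone in $k$; on
Euclidean inputs it is, and the tests pin that regime.)

## The synthetic generator: what it emulates

`synthSpec()` fixes the study conditions; all generators are pure
functions of the spec (seed mandatory, caller's RNG stream untouched).
Defaults emulate a 20-subject group on a 90-region atlas.

* `gen_correlated_timeseries`: AR(1)-filtered Gaussian signals whose
  innovations carry a planted correlation structure via Cholesky. With
  a common AR coefficient the stationary zero-lag correlation equals
  the innovation correlation, so the planted matrix is exactly the
  recovery target while the autocorrelation still inflates the
  effective-df correction — the two statistical complications the
  connectivity module must handle, in their minimal form. Default AR
  coefficient 0.4 (typical of band-limited hemodynamic signals at
  ordinary repetition times); default 150 time points (a 5-minute
  resting recording at 2 s sampling); non-positive-definite targets
  are repaired to the nearest correlation matrix with a warning.
* `gen_multiplex`: a Bernoulli(0.15) backbone mask whose edges carry
  graded true strengths — lognormal jitter (sd 0.15 on the log scale)
  around `backboneStrength = 0.6` — shared across layers. Each subject
  expresses each backbone edge with probability
  `backbonePrevalence = 0.7` and attenuates it by a downward
  half-lognormal factor; spurious noise edges (per-layer
  Bernoulli(0.1) on non-backbone pairs, proximity uniform in
  $(\epsilon, 0.4]$) differ across subjects; everything else sits at
  the floor $\epsilon$. Three of these choices are load-bearing:
  * **graded strengths** make the ground-truth metric non-trivial
    (with a constant-strength backbone all truth distances are hop
    counts and rank comparisons degenerate into ties);
  * **mid-range strengths** keep proximities away from 1, where the
    reciprocal isomorphism sends distances to 0 and the closure routes
    every path through near-ceiling edges, degenerating the geometry
    for every method at once;
  * **expression variability** (prevalence < 1, downward attenuation)
    is the inter-subject functional heterogeneity that motivates
    algebraic aggregation in the first place: the entrywise mean
    confounds an edge's strength with its prevalence across subjects,
    while the entrywise distance-minimum recovers the strength from
    the subjects that express it. With jitter-only layers (prevalence
    1, symmetric jitter) the mean is simply the more efficient
    estimator and averaging would match or beat the algebraic route —
    the regime the method was never claimed for.
* `gen_modality_pair`: network B equals network A except that every
  edge incident to `nPerturbedNodes = 5` randomly chosen nodes is
  weakened, in distance space, by `perturbationMagnitude = 2` times
  the sd of A's closed embedded edge distribution. Expressing the
  planted effect in SD units of the embedded distribution makes the
  generator's effect size commensurate with the detector's threshold
  units: a 2 SD perturbation should land perturbed nodes near
  displacement 2 and leave others near
  $\sqrt{5/89} \cdot 2 \approx 0.47$, which is what the pipeline
  recovers. The perturbation weakens (never strengthens) so proximity
  stays inside $(0, 1)$.

What the generator does **not** emulate: anatomically informed
topology (spatial embedding, hemispheric symmetry, hubs), realistic
hemodynamic forward models, measurement noise correlated across
regions, and any coupling between the time-series generator and the
multiplex generator. Passing tests therefore demonstrate that the
algebra, the embedding and the detection behave as specified under
controlled violations — not that any particular empirical dataset will
separate as cleanly.

## Numerical choices

* Matrix equalities at $10^{-9}$ absolute unless stated; isomorphism
  round trips at $10^{-12}$; argmin tie credit at $10^{-12}$.
* The closure fixpoint is detected by exact equality of successive
  accumulated squarings — valid because, with a zero diagonal,
  squaring is monotone non-increasing and the entry values live in the
  finite set of path sums.
* $+\infty$ is a first-class weight: $\infty \otimes x = \infty$,
  $\oplus$ treats it as identity, disconnected components stay at
  $\infty$ through closure, and $\infty \mapsto w = 0$ under the
  inverse isomorphisms. Exact zero proximities are refused by default
  (`zeroPolicy = "infinite"` opts in), since normalized networks
  cannot produce them and they usually indicate a data error.
* Off-diagonal $|r| = 1$ raises (duplicated signals) rather than being
  clipped silently.
* CSV serialization uses `%.17g`, making write/read round trips
  bit-exact; `inf` encodes $+\infty$.

## Known limitations

* The closure is $O(n^3 \log n)$ in the worst case via repeated
  squaring; fine at connectome scale ($n \sim 100$), not intended for
  $n \gg 10^3$.
* Hypersphere detection is a calibrated heuristic, not an inferential
  procedure: z-scoring gives the radius SD units, but no per-node
  p-values or multiplicity control are provided, by design.
* Layer contribution is defined at the aggregation step only (see
  above); a path-membership notion of contribution would require a
  canonical tie-breaking rule the algebra does not supply.
* The average-aggregation comparison implemented here concerns rank
  recovery of a planted backbone metric; it is not a general statement
  that averaging is inferior for every estimand.
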
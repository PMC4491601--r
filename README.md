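# tropnet

Aggregation, metric embedding and comparison of same-node weighted
networks under the (min, +) tropical semiring — built for multimodal
connectomics, where a group of per-subject functional networks must be
condensed into one representative network and compared against a
structural network defined on the same atlas regions.

## The method

All networks share one node set (e.g. 90 atlas regions). Edge weights
live in one of two isomorphic spaces:

- **proximity space**: `w ∈ [0, 1]`, larger = more strongly connected;
- **distance space**: `d ∈ [0, ∞]`, smaller = closer, obtained by the
  order-reversing map `d = 1/w − 1` (or `d = −log w`).

The pipeline is:

1. **Connectivity** (optional, from regional time series): zero-lag
   Pearson correlation `r_ij = ⟨x_i(t) x_j(t)⟩` of standardized signals,
   variance-stabilized by Fisher's transform
   `Z = ½ ln((1+r)/(1−r))`. Because autocorrelated series violate the
   independence assumption of the usual test, significance uses an
   effective sample size per pair,
   `1/df_ij = 1/N + (2/N) Σ_τ ((N−τ)/N) r_ii(τ) r_jj(τ)`,
   and the null `Z ~ N(0, 1/(df−3))`.
2. **Normalization**: one affine map sends the off-diagonal range of the
   raw weights onto `[ε, 1−ε]` (default `ε = 0.01`), keeping boundary
   vertices from merging or becoming isolated while preserving order.
3. **Aggregation** of a multiplex (one layer per subject), in distance
   space, by entrywise `⊕ = min`: `N* = N₁ ⊕ … ⊕ N_k`. The classical
   alternative — entrywise averaging — is also provided.
4. **Metric embedding**: the closure
   `N_embedded = N* ⊕ N*² ⊕ … ⊕ N*^r` under the semiring
   `(ℝ⁺₀ ∪ {+∞}, min, +)`, iterated to its fixpoint. This is the
   all-pairs-shortest-path generalization: it enforces the triangle
   inequality and places every network in a common metric space.
   Per-layer contribution to the aggregate (argmin credit) identifies
   subjects that contribute many, few or no edges — outlier layers.
5. **Comparison** of two embedded modalities: z-score each embedded
   edge distribution, form the difference grid `M = |z(A) − z(B)|`, and
   flag nodes whose displacement from the origin of the difference
   space exceeds a hypersphere radius `s` (in SD units). Classical MDS
   projects the grid to 3D for exploratory visualization only.

## Worked example

Generate a pair of 90-node networks in which the edges incident to five
planted nodes are weakened by 2 SD of the embedded edge distribution,
then recover them:

```r
library(tropnet)

pair <- genModalityPair(synthSpec(seed = 42))
res  <- compareModalities(pair$a, pair$b, radii = c(1, 1.2))

res$grid
#> DifferenceGrid: 90 nodes, displacement range [0.385, 1.62] SD (rms norm)
res$reports[["s1"]]
#> DetectionReport: radius s = 1 SD; 85 inside, 5 outside
#>  outside: node4, node5, node22, node36, node37
head(sort(displacement(res$grid), decreasing = TRUE), 7)
#>    node36     node5     node4    node37    node22    node87    node40
#> 1.6198636 1.5971704 1.5490156 1.5127876 1.5079524 0.8682327 0.6332840
pair$perturbed
#> [1] "node4"  "node5"  "node22" "node36" "node37"
```

The five planted nodes sit 1.5–1.6 SD from the origin — outside the
`s = 1` hypersphere — while the 85 untouched nodes stay inside; the
displacement gap (1.51 vs 0.87 for the nearest untouched node) is the
detection margin.

Aggregating a 20-subject multiplex ensemble and embedding it:

```r
mx  <- genMultiplex(synthSpec(seed = 42))
emb <- embedGroup(mx$multiplex, method = "algebraic")
emb$embedded
#> DistanceNetwork: 90 nodes, off-diagonal range [0.05243, 1.816], metrically closed (reciprocal)
emb$contribution
#> LayerContribution: 4005 aggregate edges over 20 layers
```

A command-line shell over the same functions lives in
`inst/cli/tropnet.R` (subcommands `connectivity`, `aggregate`,
`compare`, `synth`), reading and writing labeled CSV matrices with JSON
provenance sidecars.

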
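---
title: "Methods: co-occurrence network stability analysis with reefnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence network stability analysis with reefnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefnet)
```

## The question the pipeline answers

Heat stress restructures the bacterial community of a coral holobiont, and a
recurring claim in probiotic intervention studies is that treated corals keep
a *more stable ecological network* than untreated, stressed ones. reefnet
turns that claim into a reproducible computation. Starting from an ASV
(amplicon sequence variant) count table and sample metadata, it:

1. filters the table (relative abundance, prevalence, rarefaction),
2. compares community composition between groups by PERMANOVA on
   Bray–Curtis distances,
3. builds one signed Spearman co-occurrence network per group,
4. contrasts each network's topology with an Erdős–Rényi ensemble
   (clustering, path length, modularity, small-world coefficient),
5. classifies nodes into topological roles from within-module connectivity
   (Zi) and the participation coefficient (Pi), and
6. compares networks by bootstrapped two-sample Kolmogorov–Smirnov tests on
   node centralities.

Every stochastic stage takes an explicit seed; the pipeline derives stage
seeds from a master seed by a stable hash of the stage name, so a full run is
reproducible byte for byte.

## Models and statistics

### Filters

ASVs with total count below 0.005% of the table's grand total are dropped
(the grand-total convention of the standard amplicon filter). For network
construction, ASVs must be present (nonzero) in at least 30% of the samples
entering that network; "at least" is read inclusively, so presence in
exactly 30% of samples passes. Rarefaction subsamples every sample without
replacement to a common depth, by default the minimum sample total, since
amplicon studies rarely publish their exact depth.

### PERMANOVA

With $n$ samples in $k$ groups and squared Bray–Curtis distances $d_{ij}^2$,

$$SS_{total} = \frac{1}{n}\sum_{i<j} d_{ij}^2,\qquad
  SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j\in g} d_{ij}^2,$$

$$F = \frac{(SS_{total}-SS_{within})/(k-1)}{SS_{within}/(n-k)},\qquad
  R^2 = 1 - \frac{SS_{within}}{SS_{total}}.$$

The p-value counts label permutations with $F_{perm} \ge F_{obs}$, including
the observed labeling in numerator and denominator, so $p \ge 1/(n_{perm}+1)$.
The default is 999 permutations, one-way design, with a pairwise mode that
loops over group pairs without multiplicity correction (mirroring how such
comparisons are conventionally reported). The implementation agrees with
`vegan::adonis2` to numerical precision, which the test suite asserts; note
that when groups separate perfectly, random label permutations recreate the
observed partition with probability $2/\binom{n}{n/2}$, so the attainable
minimum p is approached rather than guaranteed.

Ordination is classical PCoA (eigendecomposition of the double-centered
squared distance matrix). Bray–Curtis is semi-metric, so negative
eigenvalues occur; they are reported but never embedded.

### Co-occurrence networks

Edges are pairwise Spearman correlations computed with average ranks, with
two-sided p-values from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom. A pair
becomes an edge when $|\rho| > 0.7$ **and** $p < 0.05$, both strict. No
multiple-testing correction is applied by default because the thresholding
convention this reproduces uses raw p-values; a Benjamini–Hochberg switch
exists (`adjust_p = TRUE`). Constant ASVs have no defined rank correlation
and are skipped with a message. Isolated ASVs never enter the network, and
all topology treats the graph as unweighted and unsigned — the sign and
$\rho$ ride along as edge attributes for export (GraphML for Gephi, or edge
CSV).

At $n = 10$ samples per network the t-approximated p of $\rho = 0.7$ is
about 0.024, so roughly 2.4% of all *null* pairs pass both thresholds. With
hundreds of ASVs this yields hundreds of spurious edges; that is a property
of the thresholding method itself, faithfully reproduced, and is why node
counts in such networks approach the ASV count. These noise edges are also
mutually dependent (they share the same few samples), which inflates
modularity above Erdős–Rényi levels even without planted structure — a green
"Q above the random ensemble" result at small $n$ should therefore be read
together with the network's edge count.

### Topology and null models

Per network we report node/edge counts, density, mean local clustering
(triangles over possible triangles, 0 for degree < 2), average shortest path
length over the largest connected component, and modularity Q of the
detected partition. The null ensemble is $G(n, m)$ — uniform simple graphs
with exactly the empirical node and edge counts ("respective" random
networks) — with per-replicate clustering, path length and modularity (same
greedy detector), summarized as mean ± sd.

The small-world coefficient is Humphries–Gurney sigma,

$$\sigma = \frac{C/\bar{C}_{ER}}{L/\bar{L}_{ER}},$$

computed against the $G(n,m)$ ensemble means. Many papers name a
small-world coefficient without defining it; this package defines it
prominently so the number is interpretable.

Betweenness is unnormalized shortest-path betweenness; closeness is computed
within each node's connected component; both choices are deliberate because
disconnected co-occurrence networks make the global definitions ambiguous.

### Node roles (Zi–Pi)

Modules come from deterministic greedy modularity maximization
(Clauset–Newman–Moore as implemented in igraph, with vertices sorted
lexicographically when the network is built; if the dendrogram cut ever
scores below the one-module-per-component partition, the latter is used).
For node $i$ in module $s_i$ with $k_{is}$ links inside its own module:

$$Z_i = \frac{k_{is} - \bar{k}_{s_i}}{\sigma_{k_{s_i}}},\qquad
  P_i = 1 - \sum_s \left(\frac{k_{is}}{k_i}\right)^2,$$

with the *population* standard deviation (the original role-cartography
definition) and $Z_i = 0$ when a module's within-degrees are all equal
($\sigma = 0$). Roles: network hub ($Z_i > 2.5$, $P_i > 0.62$), module hub
($Z_i > 2.5$, $P_i \le 0.62$), connector ($Z_i \le 2.5$, $P_i > 0.62$),
peripheral (otherwise). Both thresholds are strict on the high side; a node
sitting exactly on a threshold goes to the lower category and is logged,
since strict inequalities on both sides leave equality undefined.

### Network comparison

For every network pair and each of degree, betweenness and closeness, the
two-sample KS statistic $D$ and its asymptotic two-sided p-value are
computed on the raw node-attribute vectors; then both vectors are resampled
with replacement (at their original sizes) for 10,000 iterations, recording
$D$ each time, and the bootstrap distribution is reported as a percentile
interval. What exactly is "bootstrapped" in published versions of this
procedure is typically unstated; resampling attribute values is the
interpretation implemented here, and the observed-D p-value is always
reported alongside so nothing hinges on it.

## The synthetic community generator

`synthetic_spec()` + `sample_counts()` draw grouped count tables from a
Gaussian copula: a latent multivariate normal with a block correlation
matrix ($\rho_{within}$ inside planted modules, $\rho_{cross}$ between
designated connector taxa and their foreign modules, zero elsewhere) is
mapped through log-normal quantiles, closed to relative abundances, and
converted to counts by a multinomial draw at Poisson library sizes
(default mean $10^4$, emulating a typical amplicon study of ~50 samples in
4–5 groups with hundreds of ASVs). Group effects multiply mean abundance of
chosen taxa by a fold factor in one group. Because all downstream statistics
are rank- or distance-based, the marginal family is immaterial; what the
copula controls is the rank correlation, which converges to the Greiner
transform $(6/\pi)\arcsin(\rho/2)$ of the latent $\rho$, attenuated a few
hundredths by count noise and compositional closure.

Defaults were chosen once, as a realistic amplicon world, and not revisited:
library sizes Poisson($10^4$), log-normal(0, 1) abundances, 10 samples per
group in the demo design, modules of 10–15 taxa at $\rho_{within} = 0.85$,
connectors at the generator's exemplar $\rho_{cross} = 0.75$.

The generator does **not** simulate sequencing error, chimeras, taxonomy, or
overdispersed library sizes. A green test on synthetic data establishes that
the pipeline recovers structure *planted under the generator's assumptions*;
it does not establish robustness to artifacts upstream of the count table.

### Requested versus feasible correlations (PSD repair)

If the requested block matrix is not positive semi-definite, negative
eigenvalues are clipped to zero and the diagonal rescaled to one — the
standard nearest-PSD heuristic. This matters for connectors: a module at
$\rho_{within} = 0.85$ is almost a single latent factor, and a taxon
correlated with two mutually uncorrelated factors cannot exceed

$$r_{max} = \sqrt{\tfrac{1 + (m-1)w}{2m}} \approx \sqrt{w/2} \approx 0.65$$

with each (size-$m$ modules at within-correlation $w$). Requesting more
simply makes the repair shrink the connector's row to this cap. After rank
and count attenuation the connector's empirical Spearman sits near 0.5 at
$n = 20$ — *below* the 0.7 edge threshold — so planted connector edges
survive only by sampling noise. Consequently module membership is recovered
very well (adjusted Rand index ≥ 0.8 in ~94% of calibration replicates) but
connector identification via Pi is unreliable (~30% of replicates), and this
is a mathematical property of strict high-threshold correlation networks,
not an implementation defect. The acceptance suite asserts the stronger
joint claim anyway and documents its failure rather than weakening it; users
planning connector-recovery simulations should either lower the edge
threshold or plant overlapping (mutually correlated) modules.

## Numerical and design choices

- **PSD repair**: eigenvalue clipping + diagonal rescaling (above).
- **p-values at $|\rho| = 1$**: set to the smallest positive double rather
  than zero, keeping them usable in $p < \alpha$ comparisons.
- **KS with ties**: $D$ is evaluated on the pooled ECDF after whole tie
  groups; the asymptotic p-value uses the standard alternating series with
  $\lambda = D\sqrt{mn/(m+n)}$.
- **Degenerate inputs**: all-zero samples are an error naming the sample;
  constant ASVs are skipped pairs; empty edge lists yield valid empty
  networks that the pipeline logs and skips for topology; samples below the
  rarefaction depth are dropped with a message.
- **Determinism**: seeded draws save and restore the caller's RNG state, so
  library calls do not perturb user scripts; stage seeds are
  `hash(stage name) + master seed (mod 2^31 - 1)`.
- **Boundary conventions**: abundance and prevalence filters are inclusive
  at their thresholds; edge thresholds are strict; role thresholds are
  strict with ties going down. Each is asserted by a boundary test.

## Known limitations

- Spearman-threshold networks at small $n$ carry many spurious edges and
  elevated modularity (see above); the package reproduces the method, it
  does not fix it. Compositionally aware inference (SparCC-style) is out of
  scope.
- Weighted or signed clustering/modularity variants and degree-preserving
  (configuration-model) nulls are not implemented; the nulls are $G(n,m)$.
- The PERMANOVA is one-way; factorial designs must be analyzed pairwise.
- Connector recovery under strict thresholds is limited by the PSD cap
  discussed above.

## A worked demo

```{r demo, eval = FALSE}
demo <- make_demo(seed = 1, dir = tempfile())
cfg <- pipeline_config(demo$counts, demo$metadata,
                       networks = c("LT", "HT", "HTB"),
                       n_perm = 199, n_random = 100, n_boot = 1000,
                       seed = 1, out_dir = "reefnet_out")
res <- run_pipeline(cfg)
res$permanova
res$topology[, c("network", "n_nodes", "n_edges", "Q",
                 "er_modularity_mean", "small_world_sigma")]
res$connector_counts
```

The README shows this run's actual printed output.
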
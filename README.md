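# reefnet

Co-occurrence network stability analysis for coral (and other host-associated)
microbiome count tables.

## What it is for

Probiotic intervention studies in corals often conclude that treated,
heat-stressed animals retain a "more stable" bacterial ecological network
than untreated ones. reefnet makes that claim computable and reproducible.
From an ASV count table (samples × taxa) and sample metadata it runs, with
one master seed:

- **Filtering** — drop ASVs below 0.005% total relative abundance, require
  presence in ≥ 30% of samples for networks, rarefy to a common depth.
- **Community comparison** — Bray–Curtis distances
  `d(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)`, PCoA ordination, and one-way permutation
  PERMANOVA (pseudo-F, R², permutation p with the +1 convention), pairwise
  over groups.
- **Networks** — pairwise Spearman ρ (average ranks, t-approximation
  p-values); an edge needs `|ρ| > 0.7` **and** `p < 0.05` (both strict).
  Export as Gephi-compatible GraphML or edge CSV.
- **Topology vs. chance** — mean local clustering, largest-component path
  length, modularity Q, compared against a G(n, m) Erdős–Rényi ensemble,
  plus the Humphries–Gurney small-world coefficient
  `σ = (C/C_ER)/(L/L_ER)`.
- **Node roles** — within-module connectivity `Zi = (k_is − k̄_s)/σ_ks`
  and participation `Pi = 1 − Σ_s (k_s/k)²`, classified as network hub
  (`Zi > 2.5`, `Pi > 0.62`), module hub, connector, or peripheral.
- **Network comparison** — two-sample Kolmogorov–Smirnov tests on degree,
  betweenness and closeness with 10,000 bootstrap iterations.

A Gaussian-copula synthetic community generator (planted correlation
modules, connector taxa, group effects, multinomial counts at Poisson
depths) provides ground truth for every stage, so the whole pipeline is
tested against known structure.

## Worked example

```r
library(reefnet)
demo <- make_demo(seed = 1, dir = tempfile())   # 4 groups x 10 samples, 300 ASVs
cfg <- pipeline_config(demo$counts, demo$metadata,
                       networks = c("LT", "HT", "HTB"),
                       n_perm = 199, n_random = 100, n_boot = 1000,
                       seed = 1, out_dir = "reefnet_out")
res <- run_pipeline(cfg)
res$permanova
```

```
        pair        F         R2     p n_perm      seed
1  HT_vs_HTB 1.734022 0.08786969 0.005    199 668544542
2   HT_vs_LT 1.652721 0.08409627 0.005    199 668544543
3  HT_vs_LTB 1.747078 0.08847274 0.005    199 668544544
4  HTB_vs_LT 1.196297 0.06231914 0.030    199 668544545
5 HTB_vs_LTB 1.125961 0.05887081 0.100    199 668544546
6  LT_vs_LTB 1.176778 0.06136472 0.065    199 668544547
```

The heat-stressed group (HT, which carries the planted 3-fold abundance
shift) separates from every other group at p = 0.005 — the permutation
floor at 199 permutations — while the two unstressed groups (LT vs LTB) do
not separate, exactly the pattern planted by the generator.

```r
res$topology[, c("network", "n_nodes", "n_edges", "Q",
                 "er_modularity_mean", "small_world_sigma")]
```

```
    network n_nodes n_edges         Q er_modularity_mean small_world_sigma
LT       LT     300    1324 0.5163898          0.2976474          8.593670
HT       HT     300    1354 0.4980110          0.2940934          8.288419
HTB     HTB     299    1267 0.4875116          0.3040735          8.665552
```

Each empirical network is far more modular than its size-matched random
ensemble (Q ≈ 0.5 vs ≈ 0.3) and strongly small-world (σ ≈ 8.5). Note the
caveat spelled out in the vignette: at n = 10 samples per network the
`|ρ| > 0.7, p < 0.05` rule lets through ~2.4% of null pairs, so these
networks are dominated by threshold noise — faithfully reproducing the
method's behavior at this sample size.

```r
res$connector_counts
```

```
  network n_nodes n_connectors n_module_hubs n_network_hubs n_peripherals
1      LT     300           46             3              0           251
2      HT     300           42             6              0           252
3     HTB     299           57             3              0           239
```

All outputs (filtered table, distance matrix, PCoA coordinates, PERMANOVA
table, GraphML networks, role tables, topology summaries, KS comparisons,
and a log of every stage seed and filter tally) are written under
`out_dir`; re-running with the same seed reproduces them byte for byte.

There is also a CLI (`inst/exec/reefnet`) with subcommands `simulate`,
`filter`, `permanova`, `network`, `topology`, `roles`, `compare`,
`run-all`, e.g.

```sh
Rscript inst/exec/reefnet run-all --table feature_table.tsv \
    --metadata metadata.tsv --out-dir out --seed 1
```

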
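# motifclust

Tools for quantifying how network motifs are *organized* in directed
networks — not just how many there are, but how they aggregate into
clusters by sharing nodes, and in which geometric arrangements.

Network motifs such as the feed-forward loop (FFL: edges A→B, A→C, B→C)
are overrepresented building blocks of transcriptional, metabolic,
neural, ecological, and engineered networks. `motifclust` is aimed at
systems biologists and network scientists who want to go one level up
from the motif census: measure motif aggregation, classify *how* motif
pairs connect, detect evolutionary signatures such as node duplication,
and use motif-cluster membership to predict functionally important nodes
(e.g. essential enzymes in a metabolic network).

## The measures

With found instances $F = \{f_1,\dots,f_n\}$ (node sets of induced motif
occurrences), the **motif clustering coefficient** is

```
Mc = S / T,   S = Σ_{i<j} |f_i ∩ f_j|,   T = Σ_{i<j} (min(|f_i|,|f_j|) − 1)
```

so `Mc = 0` means all motifs are node-disjoint and `Mc = 1` means every
pair shares the maximum possible (for 3-node motifs, two nodes).
Homologous/heterologous variants restrict the pairs to same/different
pattern types. Two overlapping FFLs form one of exactly **12 pairwise
clustering types** (6 sharing one node, 6 sharing two); the package
enumerates this catalog for any pattern set, classifies every clustered
pair, and derives:

* the **type distribution** (fractions over clustered pairs),
* per-node **MCD** (motif clustering diversity: number of distinct types
  among the motif pairs a node belongs to),
* per-node **spin** `(k_in − k_out)/(k_in + k_out)` (producer −1 …
  receiver +1),
* significance against **null models**: Erdős–Rényi, duplication growth,
  degree-preserving rewiring, and a motif-count-preserving rejection
  sampler,
* **edge-removal robustness** of the type distribution, and
* group-size-adjusted (hypergeometric) **enrichment** of a binary node
  label across MCD values, with a top-k comparison against degree and
  betweenness.

## Worked example

```r
library(motifclust)

# three FFLs sharing a single input hub (clustering type 6)
fx <- make_type_fixture(6, k = 3)
motif_clustering(fx$network)
#> Motif clustering (patterns: ffl)
#>   instances n = 3
#>   shared nodes S = 3  max possible T = 6
#>   Mc = 0.5

type_distribution(fx$network)
#> Motif clustering type distribution (3 instance(s), 3 clustered pair(s))
#>  id count fraction
#>   1     0        0
#>   ...
#>   6     3        1
#>   ...
```

Every pair of the three FFLs shares exactly the hub (1 of the 2 possible
shared nodes), hence `Mc = 3/6 = 0.5`, and all three clustered pairs are
the shared-input type 6. The hub's MCD is 1 — it joins three pairs but
only one *type* of pair:

```r
head(mcd(fx$network), 3)
#>   node mcd
#> 1    a   1
#> 2   b1   0
#> 3   b2   0
```

A duplication-grown network carries the duplication signature (types 7,
10, 12 = duplicated input, intermediate, output):

```r
g <- duplication_growth(motif_ffl(), target_n = 30, seed = 1)
td <- type_distribution(g)
subset(td$table, count > 0)
#>    id count   fraction
#> 1   1 44550 0.33457249
#> 4   4 39600 0.29739777
#> 6   6 35640 0.26765799
#> 7   7  4950 0.03717472
#> 10 10  4455 0.03345725
#> 12 12  3960 0.02973978
```

Only the same-role sharing types (1, 4, 6 one-node; 7, 10, 12 two-node)
receive mass, because duplication copies never change a node's level in
the FFL hierarchy.

Significance of clustering is assessed against nulls that keep the motif
count fixed:

```r
motif_significance(fx$network, "Mc", n_samples = 100, seed = 1)
#> Motif significance (Mc vs motif_preserving null)
#>   observed = 0.5  null mean = 0.5467  sd = 0.2273
#>   z = -0.2053  empirical P(upper) = 0.6436  ( 100 samples, 295 restarts )
```

(On a network this tiny — 7 nodes forced to hold 3 FFLs — clustering at
`Mc = 0.5` is no more than the null expects; larger, sparser networks
with the same clustering score positive z.)

A shell entry point wrapping all commands is installed at
`inst/scripts/motifclust`:

```sh
Rscript inst/scripts/motifclust mc network.txt --motifs ffl --out mc.json
Rscript inst/scripts/motifclust types network.txt --out types.csv
```

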
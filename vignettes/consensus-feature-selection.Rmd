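---
title: "Consensus feature selection of PPI-associated functional terms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus feature selection of PPI-associated functional terms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppifun)
```

## The problem and the model

Experimentally supported protein–protein interactions (PPIs) are unordered
pairs of proteins; which molecular functions, processes, components and
pathways are *associated* with the propensity of two proteins to interact is
a question about annotations of the pair, not of either protein alone.
`ppifun` frames this as a feature-selection problem over annotation-derived
pair features and extracts a consensus set of GO terms and KEGG pathways that
discriminate interacting pairs from random protein pairs.

### Order-invariant pair encoding

Each protein $p$ is a binary vector over the catalog of $n$ GO terms and $m$
KEGG pathways: $g_i^p = 1$ iff $p$ is annotated by term $i$. A pair
$(p_1, p_2)$ must be encoded symmetrically — the orientation of an
interaction carries no information — so every term contributes two channels:

$$\big(g_i^{p_1} + g_i^{p_2},\; |g_i^{p_1} - g_i^{p_2}|\big)$$

giving a $2(n+m)$-dimensional vector per pair. The sum channel is ternary
(0 = neither annotated, 1 = exactly one, 2 = both) and the absolute-difference
channel is binary; per term only the combinations $(0,0)$, $(1,1)$ and
$(2,0)$ can occur, which the test suite verifies exhaustively. The two
channels carry complementary information: the sum counts shared annotation,
the difference flags asymmetric annotation (a receptor/ligand-style division
of labour is visible only in the difference channel).

### Balanced datasets from sampled negatives

With $N$ proteins there are $\binom{N}{2}$ unordered pairs; all non-positive
pairs are candidate negatives. At the human STRING-derived scale (6,623
proteins, 70,392 positive pairs) that is 21,928,753 pairs and 21,858,361
negatives — a ~310:1 imbalance. Instead of training one biased model, the
negative pool is split randomly and equally into $K = \max(1, \lfloor
\text{negatives} / \text{positives} \rfloor)$ disjoint subsets, each combined
with the full positive set into a balanced dataset. "Equally" is realised as
sizes differing by at most one (the pool size is generally not divisible by
$K$); the remainder goes to the first subsets via round-robin dealing after a
seeded shuffle.

### Shadow-feature relevance filtering

Each balanced dataset is filtered with an all-relevant shadow-feature
(Boruta-style) wrapper: every column is copied and row-shuffled, the shadows
are stitched to the real matrix, a random forest is fitted, and a real
feature scores a *hit* when its impurity importance exceeds the maximum
shadow importance. Hits over iterations are compared to the Binomial(k, 0.5)
null with a two-sided test — each tail at $\alpha/2$ with Bonferroni
correction over the original feature count. Significantly-above features are
accepted, significantly-below rejected and removed from later iterations; the
loop stops early when nothing is undecided. Defaults: 100 iterations,
$\alpha = 0.05$, 100 trees, and features still undecided at termination are
rejected (the conservative policy; `tentative = "median"` instead accepts
those whose median importance beats the median of the max-shadow history).
These defaults are explicit because "default Boruta" is not a reproducible
statement across implementations.

### Three ranking schemes

The per-dataset selected features are ranked three ways:

* **lasso** — the regression-form L1-penalised linear model of the 0/1 label
  on standardized features (not the logistic variant; the coefficient
  magnitude on standardized columns is the importance). The penalty defaults
  to 0.01; zero-coefficient features form an id-ordered tail.
* **gbdt** — a gradient-boosted tree classifier; the importance of a feature
  is the number of tree splits that use it. Because tree builders break
  equal-gain ties by internal column index, the fit is done in canonical
  feature-id order, making the ranking a function of feature identity alone.
* **mrmr** — greedy minimum-redundancy maximum-relevance in the *difference*
  form: the first feature maximises $I(f; y)$, each next feature maximises
  $I(f; y) - \frac{1}{|S|}\sum_{s \in S} I(f; s)$. Mutual information is the
  empirical plug-in estimate on the discrete $\{0,1,2\}$ alphabet in natural
  logarithm units — no continuous estimator is needed. Criterion values that
  are mathematically equal can differ by $\sim 10^{-16}$ depending on
  summation order, so ties are resolved at a fixed $10^{-12}$ tolerance by
  ascending feature id. mRMR is quadratic in the number of ranked features;
  `top_k` caps the greedy phase (default 500) and the remainder becomes an
  id-ordered tail.

### Rank aggregation and intersection

For one algorithm, the $K$ per-dataset lists are integrated by the
importance score. With $R_i(f)$ the rank of $f$ in list $i$ (0 when absent),
$N(f)$ the number of lists containing $f$:

$$M(f) = \frac{\sum_i R_i(f)}{N(f)}, \qquad W(f) = \frac{N(f)}{K}, \qquad
\text{score}(f) = \frac{M(f)}{W(f)}$$

Smaller is more important: a feature ranked near the top of many lists scores
low; a feature that surfaced in few datasets is penalised by $1/W$. Ties are
broken by ascending feature id (the aggregation itself is silent about
ties). Rank origin is 1. Features absent from every list have $W = 0$ and
are excluded rather than given an arbitrary score. The top $n$ (default 100)
of each algorithm's integrated list are then intersected: features found by
all three algorithms (the Venn triple class) are the strongest candidates,
the double and single classes progressively weaker. The partition satisfies
$3|\text{triple}| + 2|\text{double}| + |\text{single}| = \sum |\text{top-}n|$
on every run.

## The synthetic-data generator

`generate_synthetic()` emulates exactly the statistical structure the
pipeline assumes and nothing more: independent sparse Bernoulli annotations
per (protein, term) over both channels; a configurable set of *signal* terms
with elevated prevalence; positive pairs drawn by rejection sampling in which
a candidate pair sharing at least one signal term is always accepted and a
non-sharing pair accepted with probability $1/\text{enrichment}$. At
`enrichment = 1` positives are uniform random pairs — the null case. Every
protein is guaranteed at least one term (the pipeline discards unannotated
proteins, so generating them would only exercise the discard path), and every
term annotates at least one protein (terms exist in the data only through
annotation files, so an unattached term could not survive an I/O round-trip).

Defaults were fixed once as realistic for sparse functional annotation:
background prevalence 0.05, signal prevalence 0.2. The generator does *not*
simulate protein sequences, the GO DAG, term–term correlation, scale-free
interaction degree or annotation bias toward well-studied proteins — so a
passing recovery test demonstrates that the machinery finds planted
co-annotation signal at a realistic sparsity, not that it would rank the same
terms first on real STRING + GO + KEGG data.

Ground-truth evaluation uses two functions: `recovery_rate()` (fraction of
signal terms with at least one derived feature in the top-$n$) and
`signal_separation()` (difference of mean integrated-list rank between
background- and signal-derived features, with a permutation p-value). Any
feature absent from the integrated list is assigned the worst rank $L + 1$;
this keeps the statistic defined even when the null arm's filtering selects
nothing (every feature ties, difference 0, $p \approx 1$), which is precisely
the expected null outcome.

## Numerical and design choices

* **Pair canonicalization** — pairs are stored as (min, max) lexicographically;
  self-pairs are dropped (counted and reported): a protein paired with itself
  is not a pair of two proteins under the sampling scheme.
* **Strict threshold** — interaction scores must be *strictly* greater than
  the cutoff, matching "greater than zero" semantics for experimentally
  supported pairs.
* **Catalog order** — terms are sorted lexicographically, so feature indices
  are reproducible across runs and machines.
* **Seeding** — a single master seed derives one named stream per randomised
  sub-step (`derive_seed(seed, stream, index)`), so adding a stage never
  perturbs another stage's draws, and per-dataset work is order-independent.
* **Negative sampling** — desk-scale universes enumerate the complement
  exactly; large universes use rejection against a hash set of positives so
  the $\binom{N}{2}$ complement is never materialised.
* **Degenerate inputs** — an all-constant matrix yields an empty selection
  with a warning; a boosted fit with no splits yields an all-tie, id-ordered
  list with a warning; single-class labels are an error.
* **Sequence redundancy** — clustering of similar protein sequences is out of
  scope; the readers accept an externally filtered protein set.
* **GO propagation** — annotation maps are taken as given; annotations are
  not propagated to ancestor terms.

## Problem sizes

The bundled analysis scripts and the acceptance checks run a synthetic study
of 500 proteins, 200 GO + 30 KEGG terms, 10 signal terms, enrichment 20,
2,000 positive pairs and $K = 5$ balanced datasets of 4,000 pairs × 460
features, filtered with 50 shadow iterations of 50-tree forests — sizes
chosen so a complete two-arm study (enriched and null) runs in a few minutes
on one core while still forcing multi-subset partitioning and a feature space
two orders of magnitude larger than the planted signal. The published-scale
combinatorics (21,928,753 pairs, 21,858,361 negatives, $K = 310$) are exact
integer arithmetic and are verified at full scale.

## A small worked run

```{r example, eval = FALSE}
cfg <- run_config(
  synthetic = synthetic_config(n_proteins = 120, n_go = 40, n_kegg = 10,
                               n_signal = 4, enrichment = 20, n_pos = 300,
                               seed = 7),
  K = 2, boruta_max_iter = 25, boruta_trees = 50, top_n = 15, seed = 11)
res <- run_pipeline(cfg)
res$venn
#> venn_partition: 4 in all three, 0 in exactly two, 0 in one
recovery_rate(res$truth, res$tops$mrmr, 15)
#> [1] 1
```

## Known limitations

* The Venn stage requires all three algorithms; with fewer configured, the
  integrated lists are still produced but no partition is computed.
* Boruta decisions are all-relevant: a noise feature that is genuinely
  label-correlated in a finite sample may legitimately be accepted.
* The library boosted-tree fit is reproducible (single-threaded, seeded) but
  its split-count importances are a heuristic; only their ranks are used.
* mRMR's greedy phase is $O(k \cdot p)$ mutual-information evaluations; at
  very large selected-feature counts the `top_k` cap trades tail resolution
  for time (the tail is id-ordered, i.e. effectively unranked).
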
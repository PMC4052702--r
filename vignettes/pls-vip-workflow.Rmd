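---
title: "PLS-VIP differential expression with a permutation-based FDR"
author: "plsdex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PLS-VIP differential expression with a permutation-based FDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem and the model

`plsdex` analyses two-group expression studies — a probes × samples matrix
of log2-scale, already-normalized intensities plus a binary disease-status
label per sample — in settings where samples are few (tens) and probes are
many (thousands to tens of thousands). Per-probe variance or regression
tests treat every probe in isolation and cannot absorb sample-level
structure that is not in the design, such as array- or batch-specific
factors. Partial least squares (PLS) instead models all probes jointly:
it extracts latent variables — linear combinations of probes — that
maximize covariance with the disease status, and ranks probes by how much
they contribute to those components.

With a single binary response, the NIPALS algorithm reduces to the PLS1
recursion. Writing $X$ for the $n \times p$ autoscaled design matrix and
$y$ for the centered 0/1 status, component $a$ is

$$
w_a = \frac{X_a^\top y_a}{\lVert X_a^\top y_a \rVert},\quad
t_a = X_a w_a,\quad
p_a = \frac{X_a^\top t_a}{t_a^\top t_a},\quad
q_a = \frac{y_a^\top t_a}{t_a^\top t_a},
$$

followed by deflation $X_{a+1} = X_a - t_a p_a^\top$ and
$y_{a+1} = y_a - q_a t_a$. The response sum of squares explained by
component $a$ is $SSY_a = q_a^2\, t_a^\top t_a$, and deflation conserves
$\lVert y\rVert^2 = \sum_a SSY_a + \lVert y_{res}\rVert^2$ — a property the
test suite asserts. Probe importance aggregates the squared weights across
components, weighted by explained response variance:

$$
VIP_j = \sqrt{\;p\,\frac{\sum_a SSY_a\, w_{ja}^2}{\sum_a SSY_a}\;},
\qquad \sum_j VIP_j^2 = p .
$$

The normalization identity $\sum_j VIP_j^2 = p$ holds exactly under
unit-norm weight columns and is the package's cheapest self-check; it is
asserted to $10^{-6}$ relative on every fitted model in the tests.

Significance is assessed by an empirical null: the class labels are
shuffled uniformly at random (class sizes preserved), the full PLS + VIP
pipeline is recomputed on the unchanged $X$, and the resulting VIP vectors
are pooled across permutations. For a probe with observed VIP $v_j$,

$$
\widehat{FDR}_j = \min\!\left(1,\;
  \frac{E_{perm}\!\left[\#\{k : vip^{null}_k \ge v_j\}\right]}
       {\#\{k : v_k \ge v_j\}}\right),
$$

with closed ($\ge$) tail counts so ties act conservatively, followed by a
q-value-style monotonization (each probe takes the minimum raw estimate
over probes with smaller-or-equal VIP) so that a larger VIP never carries
a larger FDR. Probes with FDR strictly below the threshold are selected,
and each selected probe is labeled *up* (overexpressed in patients) or
*down* (depressed) by comparing raw log2 group means.

Downstream, selected genes are tested for term over-representation with
the upper-tail hypergeometric probability
$P(X \ge k) = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$
against the annotated-platform universe, and an interaction network is
induced on the selected genes (an edge survives only if both endpoints are
selected), with hubs defined as nodes of degree strictly greater than the
threshold.

## A worked run

```{r workflow, eval = FALSE}
library(plsdex)

cfg <- syntheticConfig(seed = 1)
paths <- simulateStudy(cfg, "study")
run <- runPipeline(list(
  expression = paths$expression, labels = paths$labels,
  annotation = paths$annotation, edges = paths$edges,
  outdir = "study/out", nPermutations = 2000, seed = 1))
run$report$n_selected
run$topTerms
hubGenes(run$network)
```

Every stage is also exposed on its own (`autoscale()`, `nipalsPls()`,
`vip()`, `permutationNull()`, `empiricalFdr()`, `probeDirection()`,
`selectDE()`, `enrichTerms()`, `topTerms()`, `buildNetwork()`,
`hubGenes()`, `exportNetwork()`), reading and writing plain TSV so any
intermediate can be inspected or re-entered.

## Parameters that matter

| parameter | default | rationale |
|---|---|---|
| `nComponents` | 3 | three latent variables separate patient and control samples well in this family of designs; no automatic selection criterion is applied |
| `nPermutations` | 10000 | the analysis-scale default; tests use a few hundred, which leaves the pooled expectation stable because every permutation contributes a full VIP vector |
| `fdrThreshold` | 0.05 | strict inequality: FDR exactly at the threshold is not selected |
| `scale` | `TRUE` | column autoscaling (center + unit variance); the VIP identity and the usual VIP > 1 rule of thumb presume it. Centering-only is available via `scale = FALSE` |
| `hubThreshold` | 10 (exclusive) | a hub has degree strictly greater than 10 — "more than ten interactions" read literally |
| `topKTerms` | 10 | conventional reporting depth for enrichment tables |
| NIPALS `tol` | 1e-12 | early-stop tolerance on $\lVert X_a^\top y_a\rVert$; extraction stops with a warning when the residual response is exhausted or rank runs out |

## What the synthetic generator emulates

`syntheticConfig()` defaults encode the two-group microarray design the
package targets: 23 patients vs 11 controls, 1000 probes with baselines
uniform on log2 6–12, Gaussian per-probe noise with SD 0.5, and 50 planted
probes shifted by ±1.0 log2 units (a quarter up, mirroring the common
minority of overexpressed genes). The generative model is

$$
x_{js} = \mu_j + \delta_j \cdot class_s + \gamma_j b_s + \varepsilon_{js},
$$

with an optional latent array factor $b_s$ (`confounderSd`) carrying
standard-normal probe loadings, class-balanced by default and optionally
class-correlated. The annotation generator plants one term that
deterministically contains 80% of the DE genes over a 10% base rate; the
edge generator grows a preferential-attachment backbone over the DE genes,
forces two designated hubs to degrees 20 and 12 within the DE-induced
subgraph, and rewires any other DE gene above the hub threshold so the
planted hubs are exactly identifiable. All three generators draw from
seed-derived streams (seed, seed+1, seed+2), so studies are reproducible
probe-for-probe.

What the generator does **not** emulate: probe-level (CEL) data and its
normalization, probe-sequence effects, RNA-degradation artifacts,
heteroscedastic per-probe noise (available only as an option), correlated
co-expression blocks, and realistic ontology structure (annotations are
flat gene–term pairs; no ancestor propagation). Passing tests therefore
demonstrate algorithmic correctness and calibration under a clean Gaussian
two-group model, not performance on real arrays.

## Numerical and design choices

* **Preprocessing.** Autoscaling plus 0/1-coded, centered response.
  Zero-variance probes cannot be scaled and are dropped with a record in
  the model's preprocessing slot. Scaling is *not* recomputed inside
  permutations: it does not depend on the labels, so only $y$ changes
  under the null.
* **FDR estimator.** The pooled tail-ratio construction above, chosen over
  per-probe permutation p-values: pooling lets a few hundred permutations
  stabilize the expectation by borrowing across the probe axis, and the
  running-minimum monotonization resolves the occasional non-monotone raw
  estimate. Degenerate permutations (no response variance explained) are
  recorded as all-zero VIP rows — a conservative convention that can only
  lower the null tail.
* **Ties.** Tied VIP values receive identical FDR (closed tail counts) and
  are never jittered; tied group means are labeled *down* with a warning;
  tied enrichment p-values rank by larger overlap, then term id.
* **Direction.** From raw log2 group means rather than model loadings —
  the simplest reproducible rule, independent of component rotation.
* **Hypergeometric tail.** Delegated to `stats::phyper`, which is
  log-space stable for large universes; bound violations are rejected by
  name before the call.
* **Graphs.** Edges are canonicalized (sorted endpoints) before
  de-duplication because interaction extracts in the wild are directional
  and duplicated; degree counts distinct neighbors, not interaction
  records.

## Known limitations

* **The pooled VIP null is conservative in strong-signal regimes.** The
  observed fit's VIP normalization ($\sum_j VIP_j^2 = p$) divides by a
  weight norm that the true signal inflates, while each permutation's VIPs
  are normalized against a null-scale norm. When a sizable fraction of
  probes carries real effect, observed VIPs are compressed relative to the
  null scale, the estimated FDR exceeds the realized false-discovery
  proportion by a wide margin, and moderately shifted probes near the
  detectability boundary are missed. The acceptance checks quantify this
  at the default design: realized FDP is 0 while only about two-thirds of
  planted probes are recovered at FDR < 0.05. Selection is trustworthy but
  deliberately cautious; when recall matters more than the FDR guarantee,
  inspect the VIP ranking itself.
* **A latent array factor widens the null rather than the hit list.**
  Label shuffles that happen to align with a strong hidden factor produce
  heavy pooled null tails, so selection under such a factor becomes very
  conservative — the package's robustness shows as maintained
  false-discovery control (where per-probe t-tests with BH can be swamped
  by a class-correlated factor), not as higher sensitivity.
* Probe-to-gene mapping is taken as given (synthetic studies use a 1:1
  map); multi-probe genes are collapsed by "any probe selected".
* Enrichment reports raw p-values by default (a Benjamini–Hochberg column
  is optional), and the annotation is treated as flat — no ontology DAG
  semantics.
* The expression input must already be normalized, log2-scale data;
  probe-level normalization is out of scope by design.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on generated data:
models up to 30 samples × 200 probes for the VIP identity, exhaustive
oracles at $n, p \le 10$ (PLS1) and $N \le 12$ (hypergeometric), 20
replicate null studies of 1000 probes × 20 samples at 200 permutations for
calibration, and the default 34-sample, 1000-probe study (200 permutations
in tests, 10000 in the acceptance script) for end-to-end recovery. These
sizes were chosen so a complete run stays comfortably interactive on a
laptop while keeping every Monte-Carlo margin wide relative to its
tolerance.
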
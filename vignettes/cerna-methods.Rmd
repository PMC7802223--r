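---
title: "ceRNAnet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ceRNAnet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAnet)
```

## Scope

`ceRNAnet` implements the classical screening cascade for competing
endogenous RNA (ceRNA) inference in a two-condition bulk RNA-seq design:
class-specific differential expression, canonical miRNA seed matching, a
Spearman anti-correlation screen, a Pearson co-expression screen, an
upper-tail hypergeometric shared-sponge test, and assembly of the
tripartite circRNA–miRNA–mRNA network. It deliberately excludes upstream
read processing (alignment, circRNA/miRNA discovery), partial-correlation
ceRNA variants, and any thermodynamic or conservation-based target
scoring.

## The inference model and its assumptions

The cascade treats a triad (circRNA *c*, miRNA *m*, mRNA *r*) as a ceRNA
module when, across **all** samples of both groups pooled:

* *m* targets both *c* and *r* (seed match of at least the configured
  stringency), and all three features are differentially expressed;
* `SCC(m, c) < -0.7` and `SCC(m, r) < -0.7` (strictly);
* `PCC(c, r) > 0.9` (strictly);
* the hypergeometric tail probability of the miRNA-set overlap of *c* and
  *r* is strictly below 0.05.

Assumptions worth stating explicitly:

* **Pooling both groups** into one correlation is what makes a
  condition-driven sponge visible with n = 3 + 3: the between-group
  signal dominates the rank structure. The cost is that any
  condition-responsive feature pair is correlated; the targeting
  requirement and the sponge test carry the burden of specificity.
* **Correlation on `log2(CPM + 1)`.** CPM is plain library-size
  normalization; no TMM/upper-quartile correction is applied (declared
  non-goal). Under strong asymmetric regulation CPM is composition-biased
  — see the generator section, which is designed so that this bias does
  not contaminate the null features.
* **Coefficient-only filters.** No p-values are attached to the
  correlations; with six samples a rank correlation takes few distinct
  values and the screening thresholds (−0.7, 0.9) are read as literal
  strict inequalities.

## Differential expression

Per feature, fold change is `log2((CPM_trt + p) / (CPM_ref + p))` with
pseudocount `p = 1` (avoids division by zero; the default CPM scale makes
it numerically negligible). The default test is **Welch's t** on
`log2(CPM + 1)`; it replaces the negative-binomial machinery of dedicated
DE packages, which is out of scope here, trading fidelity for
transparency. Two practical notes:

* **Zero-variance features** (identical transformed values in both
  groups) get `p = 1` and are never significant.
* **Small-n degrees of freedom.** With 3 samples per group the
  Welch–Satterthwaite df is at most 4 and collapses toward 2 when one
  group's variance estimate dominates. Even a 16-fold effect can then
  land at `p ≈ 5e-3`, which survives a raw `p < 0.05` gate but can miss
  `FDR < 0.05` among m = 500 features. This is an honest property of the
  declared test, not a bug; it shapes the generator defaults below.

An exact **label-permutation test** (absolute difference of group means,
full enumeration) is provided but requires ≥ 4 samples per group: with
3 vs 3 only 20 assignments exist and the smallest attainable two-sided p
is 0.1.

The significance gates are class-specific: fold change ≥ 2 plus raw
`p < 0.05` for circRNA and miRNA, fold change ≥ 2 plus BH `FDR < 0.05`
for mRNA (`de_thresholds(use_fdr = TRUE)`). Both gates are exposed so
users can apply FDR uniformly if they prefer.

## Target prediction

Canonical seed classes on the target read 5'→3':

| type    | target-side string                      | length |
|---------|------------------------------------------|--------|
| 6mer    | revcomp(miRNA 2–7)                       | 6      |
| 7mer-A1 | 6mer + `A` opposite miRNA position 1     | 7      |
| 7mer-m8 | revcomp(miRNA 2–8)                       | 7      |
| 8mer    | 7mer-m8 + the A1 `A`                     | 8      |

The `A` opposite position 1 is a literal adenosine on the target
regardless of the miRNA's first base. Overlapping classifications at one
6mer-core locus collapse to the maximal type. The default minimum
stringency is `7mer-A1`. circRNA sequences are scanned as linear strings
by default; `circular_targets = TRUE` appends the first 7 nt so
back-splice-junction-spanning sites are seen (off by default because the
upstream quantification rarely resolves them). No conservation, context
or free-energy scoring is attempted.

## The hypergeometric kernel

`hypergeom_sf(k, K, n, N)` returns `P(X ≥ k)` for
X ~ Hypergeometric(N, K, n). For `N ≤ 30` the sum is evaluated with exact
binomial-coefficient arithmetic, so boundary-relevant rational values
(e.g. `1/20 = 0.05`) are represented exactly and the strict `< 0.05` gate
is decidable without tolerance fudging; for larger arguments terms are
accumulated in log space with a max-shift. The same kernel backs the
sponge test and the over-representation module.

**Universe choice.** The universe N for the sponge test defaults to *all
differentially expressed miRNAs* (`universe_policy = "all_de"`). The
alternative `"targeting_de"` (DE miRNAs with at least one predicted DE
target) is exposed but not default: in sparse targeting structures —
including the synthetic benchmark, where each planted miRNA targets
exactly one circRNA and one mRNA — it shrinks N to roughly the number of
triads, making the singleton-overlap p-value `1/N` too large to clear
0.05 and rendering the test degenerate. With the all-DE universe the
benchmark gives `p = 1/N ≈ 0.03`. No multiple-testing correction is
applied to sponge p-values by default, matching the plain `p < 0.05`
selection rule; a BH switch is available downstream via the exported
tables.

## The synthetic-data generator

The generator's job is to realize, at desk scale, exactly the structure
the cascade assumes, with every planted fact recorded in a ground-truth
table.

**Counts.** Negative binomial with mean μ and variance
μ + `nb_dispersion`·μ² (Poisson below dispersion 1e-8). Baselines are
log-uniform on `baseline_mean_range` (default 500–5000 expected counts).
On the log2 scale of μ:

* non-DE: `log2 b`;
* plain DE: `log2 b + L·a_s + ε`, with `L = de_log2fc` (default 4, i.e.
  16-fold — heat-shock-scale induction), `a_s` the *activation* (group
  indicator for up-features, its complement for down-features) and ε
  i.i.d. Gaussian jitter (`de_noise_sd = 0.3` log2 units);
* triad members: `log2 b + L·a_s + dir·A·c·w_s`, where `w_s` are
  deterministic within-group offsets equally spaced in ±1/3,
  `c = triad_coupling` (default 1) and `A = coupling_amplitude` (default
  1 log2 unit). The circRNA and mRNA of a triad share `dir`; the miRNA
  gets `−dir`, producing the required sign pattern.

Two deliberate design points:

* **Library-composition balance.** The activation parametrization places
  every DE feature at its low state in one condition and `b·2^L` in the
  other, with balanced up/down counts. Expected library size is then
  equal between groups, so plain CPM does not translate planted DE into
  spurious fold changes of the null features (with 15 % of features at
  16-fold, a naive one-sided parametrization shifts libraries ~2× and
  corrupts the entire null class).
* **Coupling amplitude by power calculation.** The within-group spread
  `A·w` is what the rank screens read, but it also inflates the
  within-group variance the t-test sees. Exact recovery requires a triad
  mRNA to reach `q < 0.05` among m = 500, i.e. roughly
  `p ≲ 1e-3` at rank ~30, i.e. `t ≳ 10` at ~4 df, i.e. within-group sd
  ≲ 0.45 log2 at a 16-fold effect. A = 1 satisfies this while keeping the
  0.33-log2 rank steps well above the NB noise floor (~0.16 log2 at the
  default baselines), so within-group orderings stay essentially
  monotone and planted `SCC` sits near −1. A = 1.5 demonstrably fails
  the FDR leg at some seeds; A = 1 is the documented default, not a
  per-seed adjustment.

**Sequences.** miRNAs (20–24 nt) are sampled so that no miRNA's 6mer seed
core occurs inside any other miRNA's 8mer site string. Targets
(200–2000 nt, uniform composition) are *scrubbed*: every chance
occurrence of any simulated miRNA's seed core is removed by point
mutation before the true and decoy sites are planted (planted intervals
are protected from later scrubbing passes). Consequently the predicted
edge set equals the ground-truth edge set exactly, which is what makes
"zero false triads" a meaningful assertion. The background hit rate of
*unscrubbed* random sequence is still verified against the closed form
`1 − (1 − 4^{-6})^{L−5}` in the test suite.

**Decoys.** `n_decoy_edges` (default 20) seed-match edges are planted
between non-triad features with no expression coupling, so targeting
alone cannot produce a triad; decoy endpoints avoid triad members so
decoys cannot add spurious support to a planted module.

**What the generator does not emulate** — and hence what a green test
does *not* establish: pooling noise from multi-animal libraries, isoform
and UTR structure, alignment or back-splice quantification artifacts,
feature-length biases, heteroskedastic dispersion trends, and
between-class library coupling (each class is normalized separately, as
for separately sequenced assays). A pipeline that is exact on this
benchmark can still be wrong about real data in all of those directions.

## Numerical and tie-breaking choices

* Spearman is Pearson on average ranks (ties get mean rank); the
  arithmetic keeps integer rank sums exact, so rational coefficients such
  as −7/10 are bit-exact and the strict −0.7 gate has no boundary
  ambiguity.
* Pairs with a constant expression vector have undefined correlation;
  they are excluded and counted in the run manifest
  (`negative_pairs_excluded_constant`).
* All outputs are ordered lexicographically by feature id; reruns on
  identical inputs are byte-identical (verified by hash in the acceptance
  suite).
* BH is the classic step-up `q(i) = min_{j ≥ i} m·p(j)/j`, capped at 1,
  mapped back to input order.
* The ΔΔCt utility is the textbook `2^-((ΔCt_case) − (ΔCt_ctrl))`.

## Known limitations

* Welch at n = 3 is blunt (see above); users with more replicates should
  prefer the permutation test or an external NB framework, then feed the
  resulting DE table into the network stage.
* The sponge test conditions on target sets produced by the correlation
  screen; its null is random set overlap, not a generative model of
  shared regulation.
* The correlation screens are threshold rules, not error-controlled
  tests; their operating characteristics at n = 6 are coarse and are
  characterized empirically (shuffle nulls) in the test suite.
* GO/KEGG-style enrichment is generic over-representation against
  user-supplied GMT sets; no ontology topology is used.
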
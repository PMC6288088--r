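---
title: "Methods: compositional co-occurrence inference and interaction-adjusted similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional co-occurrence inference and interaction-adjusted similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooccurnet)
```

# The problem

Amplicon surveys report read counts, and read counts only carry relative
information: each sample's counts are a multinomial draw from a closed
composition. Closure makes naive correlations between taxa untrustworthy --
if one taxon's fraction rises, all others must fall, so observed fractions
acquire spurious negative correlations regardless of how the underlying
absolute ("basis") abundances co-vary. `cooccurnet` implements a pipeline
for genus-level taxa-by-sample tables that works in log-ratio space where
this artefact can be corrected, and propagates the corrected associations
into sample-level similarity, ordination and network views.

The pipeline stages, each exposed as ordinary functions and composed by
`run_pipeline()`:

1. abundance filtering (`filter_by_abundance()`),
2. per-sample diversity (`diversity_table()`),
3. SparCC basis-correlation estimation with Dirichlet posterior resampling
   (`sparcc_estimate()`) and iterative extreme-covariance exclusion
   (`iterative_refinement()`),
4. permutation significance (`permutation_pvalues()`),
5. TINA sample similarity (`association_similarity()`, `tina_matrix()`),
6. SMACOF ordination (`smacof_mds()`),
7. thresholded network construction (`build_network()`).

# The correlation model

Let $a_{is}$ be the latent absolute abundance of taxon $i$ in sample $s$
and $f_{is}$ its observed fraction. The variation matrix

$$ t_{ij} = \mathrm{Var}_s\!\left[\log \frac{f_{is}}{f_{js}}\right] $$

is invariant to per-sample closure and depth, and decomposes as
$t_{ij} = \omega_i^2 + \omega_j^2 - 2\rho_{ij}\omega_i\omega_j$ in terms of
basis log-scale variances $\omega_i^2$ and correlations $\rho_{ij}$. Under
the sparsity assumption -- most pairs essentially uncorrelated, average
covariance small -- summing $t_{ij}$ over each taxon's partners gives a
linear system in the $\omega_i^2$ alone:

$$ \sum_{j \in P(i)} t_{ij} \;\approx\; m_i\,\omega_i^2 + \sum_{j \in P(i)} \omega_j^2, $$

with $P(i)$ the active partners of $i$ and $m_i = |P(i)|$.
`basis_correlations()` solves this $K \times K$ system directly and
recovers $\rho_{ij} = (\omega_i^2 + \omega_j^2 - t_{ij}) / (2\omega_i\omega_j)$,
clipped to $[-1, 1]$. Negative variance solutions, which can occur in noisy
or heavily pruned systems, are floored at $10^{-10}$ and flagged rather
than aborting a multi-draw run. At least four taxa are required, otherwise
the system is underdetermined.

## Dirichlet posterior resampling

Zero counts break log-ratios, and finite depth makes observed fractions
uncertain. Both are handled by modelling each sample's composition with a
Dirichlet posterior under a uniform prior: draw
$f_{\cdot s} \sim \mathrm{Dirichlet}(x_{\cdot s} + 1)$, which is strictly
positive, and repeat the whole estimation over `n_draws` such draws
(default 100), aggregating correlation matrices element-wise by the mean
(median optional; note the median requires holding all draws in memory).
Draws are indexed substreams of one seed, so any draw can be reproduced in
isolation.

## Iterative exclusion of extreme-covariance pairs

Strongly associated pairs violate the sparsity assumption that justifies
the variance solve, and their covariance leaks into every taxon's
$\omega^2$. The refinement loop therefore:

1. fits the basis model on the active pairs;
2. ranks active pairs by fitted basis covariance
   $c_{ij} = \rho_{ij}\omega_i\omega_j$ (ties broken lexicographically by
   taxon index, so runs are exactly reproducible);
3. removes the `batch` most positive and `batch` most negative pairs,
   where `batch` is 0.025% of the currently active pairs (minimum one
   pair);
4. refits, and repeats until the total covariance has stopped decreasing
   appreciably over the last 10 iterations.

Exclusion only removes a pair's $t_{ij}$ from the variance system; the
final model still reports $\rho$ for excluded pairs from the refined
variances, which is precisely how a strong pair's estimate benefits from
refinement.

**Choice of convergence statistic.** Two candidate series can drive the
stopping rule. The running sum of $|c_{ij}|$ over *active* pairs is
monotonically non-increasing (each step removes the extremes), but it can
essentially never satisfy a small relative-decrease threshold: removing
the maxima of $N$ positive summands removes at least a fraction
$2wb/N$ of the total per window of $w$ iterations with batch $b$ -- about
1.6% for 50 taxa and 0.55% for 270 taxa, always far above a $10^{-3}$
threshold -- so a rule watching this series only ends at the iteration cap
or the solvability floor, after pruning most of the matrix. The default
therefore watches the total absolute covariance of the *refit model over
all pairs*: once exclusions stop changing the fitted model this series
flattens and the windowed relative decrease drops below `rel_tol`
($10^{-3}$), typically within 15-25 iterations. The active-pair series is
still recorded in the trace (`total_covariance`) and retains its
monotonicity guarantee; `stop_stat = "active"` switches the rule to it for
comparison. The loop additionally stops at `max_iter` (500) or when a
further batch would leave fewer than $3(K-1)$ active pairs, the floor at
which the variance system stays reliably solvable.

Both readings of "highest covariance" are available: signed batches
(default: top positive and top negative separately) or
`signed_batches = FALSE` for a single batch of largest absolute
covariances.

## Significance

The significance scheme is a permutation test: each permutation shuffles
every taxon's counts across samples independently, destroying association
structure while preserving marginal count distributions, and re-estimates
the correlation matrix through the same machinery with a single Dirichlet
draw and no refinement (the full pipeline per permutation is available via
`full = TRUE`). Two-sided pseudo-p-values use the add-one correction
$p = (1 + \#\{|\rho_\mathrm{perm}| \ge |\rho_\mathrm{obs}|\}) / (1 + n_\mathrm{perm})$,
bounded below by $1/(n_\mathrm{perm}+1)$ -- with the default 100
permutations, p-values below 0.01 are not attainable. When the observed
matrix is itself compared against this fast null (as in the type-I
validation), it is computed with the same single-draw, no-refinement
settings so the comparison is like-for-like. No multiple-testing
correction is applied by default, mirroring standard practice of raw
$p < 0.05$ edge filtering in co-occurrence studies; `network_config(adjust
= "BH")` switches the edge filter to Benjamini-Hochberg adjusted values.

# TINA similarity and ordination

Abundance-based similarity treats taxa as unrelated. The weighted Taxa
INteraction-Adjusted index instead scores two samples through a
taxon-taxon similarity matrix $S$: each taxon's association profile is its
row of the correlation matrix, profiles are compared by Pearson
correlation $r^*_{ij}$ and rescaled to $s_{ij} = (1 + r^*_{ij})/2 \in
[0, 1]$, and samples $a, b$ with fraction vectors $p_a, p_b$ get

$$ \mathrm{TINA}(a,b) = \frac{p_a^\top S\, p_b}
   {\sqrt{(p_a^\top S\, p_a)(p_b^\top S\, p_b)}}. $$

This is a cosine similarity in the inner product induced by $S$:
$\mathrm{TINA}(a,a) = 1$ identically, and $S = I$ recovers plain cosine
similarity of compositions -- both serve as exact test oracles. The
correlation matrix entering $S$ is the refined SparCC estimate (the
unrefined matrix can be passed explicitly). Profile correlations include
the diagonal entries by default; `include_diagonal = FALSE` drops the two
self-entries of a pair, which matters little beyond a handful of taxa. A
taxon with a constant profile carries no association information; its
similarities are set to the uninformative midpoint 0.5 and flagged.

Ordination converts similarity to dissimilarity by $d = 1 - \mathrm{TINA}$
(the simplest monotone choice; $\sqrt{1 - \mathrm{TINA}}$, which is
Euclidean-embeddable for cosine-type similarities, is available) and
minimizes raw stress $\sigma(X) = \sum_{a<b}(d_{ab} - \|x_a - x_b\|)^2$ by
SMACOF -- iterated Guttman transforms, which majorization guarantees to
decrease stress monotonically. Defaults follow common analysis settings
(200 random starts, up to 20,000 iterations, convergence when the
per-iteration stress decrease falls below $10^{-8}$); the package's own
validation uses 4-8 starts and a few hundred iterations, which suffices at
a few dozen samples. Embeddings are identified only up to rotation,
reflection and translation, so all comparisons are made on inter-point
distances.

# Diversity indices

Three per-sample indices: Chao1 richness (classic form
$S_\mathrm{obs} + f_1^2/2f_2$, switching to the bias-corrected
$S_\mathrm{obs} + f_1(f_1-1)/(2(f_2+1))$ when no doubletons exist);
nonparametric Shannon diversity in the Chao-Shen sense -- Good-Turing
coverage adjustment $\hat C = 1 - f_1/n$, shrunken abundances
$\tilde p_i = \hat C x_i / n$, Horvitz-Thompson reweighting
$-\sum \tilde p_i \log \tilde p_i / (1 - (1-\tilde p_i)^n)$ -- which is
the standard meaning of "nonparametric Shannon" in diversity-estimation
software (the plug-in estimator is exposed separately as
`shannon_plugin()`); and the effective number of taxa $\exp(\hat H)$, the
order-1 Hill number. All entropies are in nats: the identity
"effective number = exp(Shannon)" that published tables satisfy to
printed precision only holds in nats. The estimator is undefined when
every observed taxon is a singleton (estimated coverage zero); this raises
an informative error rather than returning a number.

# The synthetic-community generator

No public count table accompanies the hindgut study design this pipeline
targets, so validation runs on generated data with known truth. The
generator draws per-sample log-abundances from a multivariate normal with
group-specific means and covariance
$\mathrm{diag}(\sigma)\,R\,\mathrm{diag}(\sigma)$, closes them by softmax,
draws a read depth uniformly from `depth_range` and samples counts
multinomially. This matches the estimation model's own assumptions
(log-scale basis correlations, unbiased multinomial sequencing), which is
deliberate: closure then induces exactly the artefact the estimator must
remove, and the planted $R$ is the recovery target.

Two fixed designs:

* **recovery** -- 50 taxa, 200 samples, read depths 10,000-122,000, five
  disjoint positive pairs at $\rho = 0.8$: the correlation-recovery
  benchmark. Planted pairs are sampled without reusing taxa, so $R$ is
  positive definite by construction; hand-built targets can be repaired by
  eigenvalue clipping at $10^{-8}$ followed by rescaling to unit diagonal
  (`nearest_psd_correlation()`), and recovery is always scored against the
  repaired matrix.
* **emulation** -- 100 taxa, 27 + 7 samples in two groups (host-associated
  "ciliate" vs "gut" content), depths 10,000-122,000, 20 taxa per group
  up-shifted by 3 log-units (roughly 20-fold, the order of magnitude that
  separates habitat-signature genera), 6 positive pairs planted within
  each group's signature set and 6 negative pairs across them at
  $\rho = 0.6$. A handful of shifted taxa cannot produce the two-block
  network bridged by negative associations, nor group-separable
  ordinations, that two compositionally distinct habitats show; broad
  mean-profile shifts are what create them, both via the planted pairs and
  via the group factor itself acting as a latent driver of pooled-sample
  correlations. This is a scaled-down stand-in for a ~270-genus,
  34-sample survey, sized so the full validation suite runs in seconds.

What the generator does *not* emulate: taxonomic misassignment, chimeras,
PCR and primer bias, overdispersion beyond multinomial (e.g.
Dirichlet-multinomial noise), phylogenetic correlation of abundances, and
zero-inflation mechanisms other than sampling. Passing recovery tests on
these data therefore demonstrates correctness of the estimation machinery
under its own model, not robustness to every artefact of real surveys.

# Validation design and problem sizes

The test suite validates each stage against independent oracles: explicit
loop-built linear systems for the variance solve, hand arithmetic and
closed forms for diversity and TINA, brute-force pair scans for ranking
and edge selection, classical metric scaling on exact Euclidean input for
SMACOF, and Monte-Carlo closed-form checks for the Dirichlet posterior.
End-to-end properties use the two fixed designs above: recovery of
planted correlations within $\pm 0.15$; permutation type-I error at the
nominal 5% (validated on 46 taxa $\times$ 50 samples, 1,035 independent
pairs); the compositional-artefact contrast on 10 independent taxa
$\times$ 1,000 samples, a size chosen so the estimator's sampling noise
($\approx \sqrt{2/n}$ per pair) sits clearly below the 0.05 assertion
bound; group-separable ordinations across 20 generator seeds; and
negative network edges bridging the two groups.

One caveat worth stating precisely: the maximum null-pair correlation
estimate across the ~1,220 unplanted pairs of the recovery design is an
extreme-value statistic. With per-pair sampling noise of roughly
$\sqrt{2/(n-1)} \approx 0.07$ at 200 samples, its expectation is about
0.25 -- for *any* estimator, including a Pearson oracle given the latent
uncomposed abundances -- so bounds materially below that are not
attainable at this sample size and are not asserted by the package's own
checks.

# Numerical and degenerate-input choices

* Strict inequalities for network edges (`|rho| > 0.5`, `p < 0.05`); a
  pair exactly at a threshold is excluded.
* Abundance filter strictly greater than the threshold, on the mean of
  per-sample relative abundances by default (one global taxon list);
  per-sample-maximum available via `method = "max"`. The filter is
  idempotent and applied before all correlation and similarity stages.
* Group abundance ratios use a symmetric pseudocount ($10^{-6}$) so taxa
  absent from one group keep finite ratios; $\log_2$ ratios are stored
  alongside.
* All ranking ties broken lexicographically by taxon index; all
  randomness drawn from named substreams of one global seed (pipeline
  reruns are bit-exact, verified on manifest checksums).
* Zero-depth samples, duplicate identifiers, negative or non-integer
  counts, misaligned taxon sets and all-singleton samples raise immediate
  errors naming the offending entry.

# Limitations

Correlation estimates at typical survey sizes (tens of samples) carry
sampling noise of order $\sqrt{2/n}$ per pair; with 34 samples that is
roughly 0.25, so individual edges near the 0.5 threshold should be read
as screened hypotheses, not confirmed interactions -- particularly since
the default edge filter applies no multiple-testing correction across the
thousands of candidate pairs. The permutation null destroys *all*
association structure, so in datasets with strong group structure much of
an observed correlation is attributable to the group factor rather than
direct interaction; the emulation design reproduces exactly this
behaviour. TINA inherits whatever bias the correlation matrix carries.
The refinement's stopping behaviour is validated empirically over seeds,
not proven.
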
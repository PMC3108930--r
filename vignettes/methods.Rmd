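---
title: "Methods: Bayes-factor prioritization of protein domains for disease phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayes-factor prioritization of protein domains for disease phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

The package scores the association between a candidate protein domain
$d$ and a query disease phenotype $p$ under the assumption that
phenotypically similar diseases are caused by functionally related
domains, where "functionally related" is operationalized as proximity in
a domain–domain interaction network.

Two profiles over the $m$ *seed phenotypes* (phenotypes with at least
one known associated domain) are built:

* the response $\mathbf{y}_p$, the phenotype-similarity scores between
  $p$ and each seed phenotype (dimensionless, in $[0,1]$; typically
  derived upstream from text mining of clinical descriptions);
* the predictor $\mathbf{x}_d$ with entries
  $x_{dp'} = \sum_{d' \in D(p')} x_{dd'}$, the summed kernel proximity
  from $d$ to the domains known to cause $p'$.

The linear model $\mathbf{y} = X\beta + \varepsilon$ with
$X = (\mathbf{1}, \mathbf{x}_d)$ and i.i.d. normal residuals is given
conjugate priors
$\beta \mid \sigma^2 \sim N(\mu_0, \sigma^2\,\mathrm{diag}(\sigma_\mu^2, \sigma_1^2))$
and $\sigma^2 \sim \text{Scaled-Inv-}\chi^2(n_0, \sigma_0^2)$. Both
marginal likelihoods (slope included / intercept only) are available in
closed form; their ratio is the Bayes factor.

## The limiting Bayes factor

Scoring uses the non-informative limit $\sigma_\mu^2 \to \infty$,
$n_0 \to 0$, $\sigma_0^2 \to 0$ with $\mu_0 = 0$ and $\sigma_1^2 = 1$.
Taking the limit in the ratio of the two conjugate marginals (the
$\Gamma$ and $(n_0\sigma_0^2)^{n_0/2}$ factors cancel, as do the
$\sigma_\mu^2$ factors) leaves

$$\log \mathrm{BF} \;=\; -\tfrac12\log(1 + \sigma_1^2 C_{xx})
 \;+\; \tfrac{m}{2}\,\log\!\frac{C_{yy}}{\,C_{yy} - C_{xy}^2/(C_{xx} + 1/\sigma_1^2)\,},$$

where $C_{xx}, C_{yy}, C_{xy}$ are centered sums of squares and
cross-products. Only centered moments enter, so the value is invariant
to shifting either profile — the flat-intercept limit makes location
irrelevant, as it should. The derivation is validated two independent
ways in the test suite: against the finite-prior marginal ratio evaluated
at $\sigma_\mu^2 = 10^6$, $n_0 = \sigma_0^2 = 10^{-6}$ (agreement within
1 %), and against a brute-force Simpson quadrature of the joint density
over $(\beta_0, \beta_1, \log\sigma^2)$ (agreement within $10^{-4}$
relative on the log scale). All Bayes-factor arithmetic is carried in
$\log_{10}$ space; profiles of length 5,000 with $|\log_{10}\mathrm{BF}|$
up to several hundred stay finite.

## Predictor standardization

`scoreCandidates()` and `runLOOCV()` rescale each candidate's proximity
profile to unit variance inside the regression (`standardize = TRUE`;
`bayesFactor()` itself defaults to the raw profile). The reason is that
with $\sigma_1^2 = 1$ the slope's shrinkage factor is
$C_{xx}/(C_{xx} + 1)$: a diffusion-kernel profile whose informative
spikes are $\approx 0.03$ has $C_{xx} \approx 10^{-3}$ and earns
essentially no Bayes factor however well it correlates with the
response, while a shortest-path-kernel profile with spikes of
$\approx 0.37$ is rewarded — the comparison across candidates and across
kernels would be dominated by raw amplitude rather than evidence.
Standardization also makes the Occam penalty
$-\tfrac12\log(1+\sigma_1^2 C_{xx})$ identical for every non-degenerate
candidate, which is what makes the permutation nulls operate at
chance level: with raw profiles, candidates that happen to carry known
associations have spikier profiles and are systematically penalized
under a null response, biasing the null AUC away from 50 %. Raw-profile
scoring remains available for sensitivity analyses.

Conventions: a zero-variance predictor (e.g. twin nodes with identical
proximities, or a domain disconnected from every seed) receives
$\mathrm{BF} = 1$ exactly — no evidence either way; a constant response
is an error, since the inverse-normal transform is undefined on it.

# Kernels and their parameters

* **Diffusion kernel** $K = e^{-\gamma L}$, $L = D - A$: computed
  exactly by symmetric eigendecomposition (no series truncation).
  $\gamma$ (dimensionless, default 0.05) controls diffusion range; rows
  of $K$ sum to 1 and the matrix is positive semi-definite. Values
  outside $(0,1)$ are permitted with a warning for robustness sweeps.
* **Shortest-path Gaussian kernel**
  $SG(u,v) = \exp\{-\beta\,SP(u,v)^2\}$: $\beta$ (per squared hop,
  default 1) sets how sharply proximity decays with path length;
  disconnected pairs ($SP = \infty$) map to 0, the formula's limit.

Self-loops in input edge lists are dropped with a warning (the Laplacian
convention needs a simple graph), keeping the endpoint as an isolated
node. Node order is the sorted order of domain identifiers, fixed at
construction, so every derived matrix is bit-for-bit reproducible.

The degree-preserving network null uses repeated double-edge swaps
(igraph's `keeping_degseq`), with 10 × |E| attempted swaps — a standard
mixing heuristic; the rewiring algorithm is our choice, as only the
degree-preservation property is prescribed.

# The inverse-normal transform

$z_i = \Phi^{-1}\!\big((r_i - c)/(m - 2c + 1)\big)$ with ascending ranks
$r_i$, ties averaged, and plotting-position offset $c = 3/8$ (Blom), the
standard choice for normal scores; $c$ is configurable through
`RankTransform`. Tie handling matters in practice: real similarity
matrices contain many tied zeros, and averaged ranks keep the transform
well defined there. With distinct inputs the output mean is 0 by
symmetry of the plotting positions.

# Evaluation

Leave-one-out cross-validation hides one association (or, in ab initio
mode, all associations of the query phenotype), then ranks the true
domain against a candidate set defined by protocol: 99 random controls
(drawn excluding the true domain and the phenotype's other known
domains), the genomic neighbourhood within 10 Mbp of the true domain's
loci (simulated linkage interval), or all network domains. Criteria:

* **precision** — fraction of runs with the true domain at rank exactly
  1; tied-top candidates (averaged rank 1.5) count as failures, a
  deliberately conservative convention;
* **mean rank ratio** — average of rank/candidate-count, in percent;
* **AUC** — disease rank ratios pooled across runs against pooled
  control rank ratios, Mann–Whitney convention with ties credited ½
  (cross-checked in tests against brute-force pairwise comparison).
  Pooling across runs (rather than averaging per-run AUCs) matches
  ROC curves built from all validation runs at once.

The query phenotype, when itself a seed phenotype, is omitted from the
profile index by default (`excludeQuery = TRUE`): its self-similarity of
1 paired with the candidate's proximity to the query's own seeds is a
leakage channel that would flatter every method. This is a choice the
data cannot make for us; the flag exposes both behaviours.

Robustness suites rerun the whole cross-validation after destroying
exactly one layer of structure: degree-preserving network rewiring (the
kernel is recomputed), association permutation preserving each
phenotype's count, or per-run similarity-profile permutation. With
informative structure removed the expected AUC is 50 %. At the problem
sizes used here (150 evaluated pairs) a single shuffle's pooled-AUC
estimate has a standard error near 2 points, so `robustnessSuite()` can
pool several independent shuffle replicates (`nReplicates`) to sharpen
the estimate; the packaged checks use 3.

Seed-sensitivity knobs mirror common robustness analyses:
`seedFraction` keeps a random fraction of the remaining associations per
run, `similarityTopFraction` keeps only the most similar fraction of
seed phenotypes.

**Fold enrichment** for gene-level validation is $b/a$ for a method that
places true entities in the top $a$ % of candidates in $b$ % of runs;
gene scores are the maximum $\log_{10}$ BF over the domains of a gene's
products.

# The SNP-proximity enrichment test

Given a genome-wide ranking, the observed count $N_0$ of reported
susceptibility SNPs lying within 5 Mbp of any top-10 domain is compared
with counts $N_i$ for $M$ random draws of 10 domains from the same
universe; $p = m/M$ where $m = \#\{i : N_i \ge N_0\}$, with no
continuity correction. A SNP counts once toward the total (SNP-level
count) even when near several domains; the per-domain breakdown
separately reports incidences in the nested categories inside / ≤ 1 Mbp
/ ≤ 5 Mbp. "Within $W$ bp" means the SNP position lies in
$[\text{start} - W, \text{end} + W]$, a closed boundary measured from
the locus boundaries (midpoint-based distance was considered and
rejected as less conventional for interval data). Domains without loci
are excluded with a warning.

# The synthetic-scenario generator

`simulateScenario()` builds the world the model assumes, with a planted
signal that is recoverable, tunable, and destroyed by each permutation
null:

1. an Erdős–Rényi domain network with mean degree 8 by default — between
   the sparse structural-interaction regime (≈ 2.3 interactions per
   domain) and the dense predicted-interaction regime (≈ 18);
   preferential attachment is available;
2. each phenotype draws its causal seed domain uniformly, without
   replacement across phenotypes while unused domains remain, so
   distinct diseases are caused by distinct domains;
3. pairwise similarity is derived from the network: the number of edges
   linking the two seed sets (self-pairs excluded) is mapped through
   $1 - e^{-\text{count}}$, scaled by `signalStrength`, perturbed by
   clipped Gaussian noise (`noiseSd`, default 0.05) and rounded to six
   decimals so fixtures round-trip byte-identically;
4. loci are tiled across a synthetic genome (5 chromosomes × 100 Mbp),
   background SNPs are scattered uniformly and 40 SNPs are planted
   within 1 Mbp of 10 designated seed domains;
5. genes map to 1–3 domains each, covering every domain.

Two features of this construction are deliberate and worth spelling out,
because simpler designs fail subtly:

* **Similarity from seed-set interactions, self-pairs excluded.** An
  earlier design embedded phenotypes in a latent space around "anchor"
  domains and took cosines. It failed the permutation-null calibration
  in several distinct ways: anchor-concentrated seeds made similar
  phenotypes share domains, whose self-proximity ($K_{dd} \approx 0.9$)
  survives degree-preserving rewiring; and hub-anchored similarity in
  scale-free graphs partially survives rewiring because rewiring
  preserves the hub core. Deriving similarity from the *interactions
  between distinct seed domains* puts all planted signal into the
  wiring itself, which rewiring destroys exactly.
* **Unique seeds and exchangeable association counts.** If disease
  domains carry more (or fewer) associations than random controls,
  their profiles are systematically spikier (or smoother) and the
  association/similarity nulls drift off 50 %. One unique causal domain
  per phenotype, drawn uniformly, keeps true domains and controls as
  exchangeable as the protocol allows. The real association rate is
  closer to 1.4 domains per phenotype; `seedCountProbs` exposes
  multi-domain diseases for users who want them, at some cost in null
  calibration.

What the generator does **not** emulate: the heavy-tailed degree
distribution of curated interaction databases interacting with
text-mining similarity (similarity here is exactly network-derived plus
noise); diseases sharing causal domains (by default); realistic
marginal distributions of the similarity scores; linkage disequilibrium
or realistic SNP density. Passing tests on this generator therefore
demonstrate that the implementation recovers the signal the model
posits when it is present and reports chance when it is absent — not
that the model is true of any real database.

All randomness flows from one scenario seed through derived substreams,
so bundles are byte-identical across runs; `writeFixtures()` /
`readInputBundle()` round-trip the plain-text formats losslessly.

# Problem sizes and determinism

The packaged checks use scenarios of 400 domains × 150 phenotypes for
end-to-end claims (cross-validation, nulls, parameter sweeps, GWAS
calibration at $M$ = 500–1000 over 200 repetitions) and 40–200 domains
for unit-level properties; the full suite runs in about a minute. Every
stochastic operation takes an explicit seed, restores the caller's RNG
state, and derives per-run substreams below $2^{31}$, so identical
inputs and seeds give byte-identical outputs everywhere, including the
command line.

# Known limitations

* The limiting Bayes factor with standardized predictors makes ranking
  within one query monotone in $R^2$; the Bayesian machinery still
  matters for the *magnitude* of evidence, for finite priors, and for
  cross-query comparability, but rank-based comparisons against the
  non-Bayesian baseline are tied by construction under the default
  settings. Raw-profile scoring (`standardize = FALSE`) restores the
  distinction at the cost of amplitude sensitivity.
* Phenotype similarities are consumed as given; computing them from
  clinical text is out of scope.
* The landscape computation is dense (phenotypes × domains Bayes
  factors); chunked computation with checkpoint files supports long
  runs, but no sparse shortcuts are attempted.
* Multi-predictor models (two-domain interaction effects), MCMC
  marginal likelihoods under non-conjugate priors, and rank combination
  across data sources are not implemented.
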
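# domainRBF

Ranks candidate **protein domains** (Pfam-style families) for a query
**disease phenotype** by a Bayes factor, on the premise that
phenotypically similar diseases are caused by functionally related —
network-proximal — domains.

Most disease-gene prioritization works at the gene level; this package
works one level below. Protein domains are the units that carry function,
and the same domain recurring in many proteins can link molecularly
heterogeneous diseases. Given a domain–domain interaction network, a set
of known domain–phenotype associations and a phenotype–phenotype
similarity matrix (typically text-mining derived), the package scores any
(domain, phenotype) pair and ranks whole candidate lists. It is intended
for computational biologists studying the molecular basis of Mendelian
and common diseases.

## The model

For a query phenotype *p*, the **phenotype similarity profile**
*y<sub>p</sub>* holds the similarities between *p* and every seed
phenotype (phenotypes with at least one known associated domain). For a
candidate domain *d*, the **domain proximity profile** *x<sub>d</sub>*
holds, over the same phenotypes,

&nbsp;&nbsp;&nbsp;&nbsp;*x<sub>dp'</sub>* = Σ<sub>d' ∈ D(p')</sub> *x<sub>dd'</sub>*,

the summed network proximity from *d* to the domains known to cause
*p'*. Proximity *x<sub>dd'</sub>* comes from one of two kernels on the
interaction network:

* **diffusion kernel (DK)**: K = e<sup>−γL</sup> with Laplacian
  L = D − A (default γ = 0.05);
* **shortest-path Gaussian kernel (SG)**:
  SG(u,v) = exp{−β·SP(u,v)²} (default β = 1).

The response is made Gaussian by a rank-based inverse-normal transform
z<sub>i</sub> = Φ<sup>−1</sup>((r<sub>i</sub> − c)/(m − 2c + 1)) (Blom
offset c = 3/8), then the simple linear regression **y** = Xβ + ε,
X = (1, x<sub>d</sub>), is solved with conjugate priors
β | σ² ~ N(μ₀, σ²·diag(σ<sub>μ</sub>², σ₁²)) and scaled-inverse-χ² σ².
The score is the **Bayes factor** — the ratio of marginal likelihoods of
the slope-included versus intercept-only model. In the default
non-informative limit (σ<sub>μ</sub>² → ∞, n₀ → 0, σ₀² → 0, μ₀ = 0,
σ₁² = 1) it has the closed form

&nbsp;&nbsp;&nbsp;&nbsp;log BF = −½·log(1 + σ₁²·C<sub>xx</sub>) +
(m/2)·log[ C<sub>yy</sub> / (C<sub>yy</sub> −
C<sub>xy</sub>²/(C<sub>xx</sub> + 1/σ₁²)) ]

with centered sums of squares/cross-products C. Candidates are ranked by
descending log₁₀ BF; by default each profile is standardized to unit
variance inside the regression so that candidates are compared by profile
shape rather than raw kernel amplitude (see the methods vignette).

Around the core score the package provides leave-one-out cross-validation
(random-control, simulated linkage-interval and genome-wide protocols;
precision / mean rank ratio / ROC AUC), three permutation-null
robustness suites (degree-preserving network rewiring, association
shuffling, similarity-profile shuffling), ab initio inference (all of a
disease's known domains withheld), gene-level scores (maximum BF over a
gene's domains, with fold-enrichment evaluation), a genome-wide
phenotype × domain landscape, a SNP-proximity permutation test for GWAS
support of top-ranked domains, and a fully seeded synthetic-scenario
generator.

## Worked example

```r
library(domainRBF)

scenario <- simulateScenario(nDomains = 200, nPhenotypes = 80,
                             signalStrength = 0.9, seed = 42)
net <- scenario$network
net
#> DomainNetwork with 200 domains and 800 interactions
#>   mean degree: 8

prox <- diffusionKernel(net, gamma = 0.05)

## ab initio: pretend P0007's genetic basis is unknown, rank all domains
ranking <- scoreCandidates("P0007", domainIds(net),
                           scenario$associations, prox,
                           scenario$similarity, mode = "ab_initio")
head(ranking, 5)
#>   domain   log10bf   rSquared rank rankRatio
#> 1  D0193 6.0599571 0.33969623    1     0.005
#> 2  D0023 0.9532028 0.10629470    2     0.010
#> 3  D0020 0.7724188 0.09669077    3     0.015
#> 4  D0036 0.4274951 0.07808395    4     0.020
#> 5  D0142 0.4131648 0.07730278    5     0.025

domainsOf(scenario$associations, "P0007")
#> [1] "D0193"
```

The true causal domain ranks first out of 200 with log₁₀ BF ≈ 6.1: the
data favour the association by a factor of about 10⁶ over the
intercept-only model, while the runner-up only reaches BF ≈ 9.

```r
ev <- runLOOCV(scenario$associations, prox, scenario$similarity,
               protocol = "random_control", nControls = 99, seed = 42)
ev
#> EvaluationSummary: 80 runs (0 skipped)
#>   precision       88.75 %
#>   mean rank ratio  3.46 %
#>   AUC             97.51 %
```

Held-out associations are recovered at rank 1 in 88.75 % of runs against
99 random controls; the SNP-proximity permutation test on the same
scenario (`snpEnrichmentTest`) gives p = 0 at M = 1000 for the planted
top domains.

A thin command-line front end over the same functions lives at
`inst/scripts/domainrbf.R` (subcommands `simulate`, `kernel`,
`prioritize`, `abinitio`, `loocv`, `gene-rank`, `gwas-enrich`,
`landscape`; stochastic commands require `--seed`).

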
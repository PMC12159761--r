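---
title: "Methods: diversity, co-occurrence networks and stability of soil microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, co-occurrence networks and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micronetstab)
```

# Scope and model of the data

`micronetstab` analyses amplicon sequence variant (ASV) count tables from
designed soil experiments — typically a small number of treatments with a
handful of replicate plots each — and asks how treatments reshape (i) the
diversity of the bacterial community, (ii) the architecture of its
co-occurrence network, (iii) the stability of that network, and (iv) the
causal pathway from treatment through soil properties and community
structure to plant performance. The package assumes counts are
compositional sequencing reads: absolute abundances are unidentifiable,
library sizes vary, and overdispersion and zeros are the norm. Everything
downstream of the count table works either on rarefied counts or on
per-sample relative abundances.

# The synthetic community generator

Because real field data cannot certify correctness, the generator plants a
known answer behind every stage.

**Count model.** Each taxon has a baseline log-abundance drawn from a
normal distribution (`base_sd`, default 1.5, giving a realistic skewed
rank-abundance curve). Sample-level latent Gaussian factors carry a block
structure: taxa in the same planted module share correlation `rho_in`,
taxa in different modules `rho_out`, implemented as a variance split over
a global factor, a module factor and an idiosyncratic term. Latent log
abundances are exponentiated and renormalised to relative abundances
(log-normal), multiplied by treatment effects (`effect_logfc` on a random
`effect_taxa_frac` of taxa per non-reference group, random sign), and then
sampled as negative-binomial counts (`dispersion`, default 0.5) at a
log-normal library size (`depth_mean` 50,000, `depth_cv` 0.3 — depths
safely above a 34,234-read rarefaction depth, so rarefaction is exercised
non-trivially). Correlation is planted on the latent scale, not on the
counts, deliberately: rank correlations are invariant under the monotone
exponential map, so Spearman-based network inference can in principle
recover the modules, while the negative-binomial sampling attenuates the
observed correlation below `rho_in`. Zero inflation arises from the
sampling model itself; no separate zero process is added.

**Metadata model.** Four latent variables — treatment score, soil,
community, plant — follow a recursive acyclic path model. Each downstream
latent is the coefficient-weighted sum of its predecessors plus Gaussian
noise calibrated so that every latent has unit variance; the coefficients
are therefore standardised path coefficients, directly comparable to what
a path model estimates. Manifest columns (nine soil covariates named after
standard soil chemistry measurements, two community-structure axes, biomass
and yield) are their latent score plus `meta_noise_sd` measurement noise
(default 0.3).

**Trees.** Random bifurcating topologies with unit-exponential branch
lengths; enough to exercise Faith's PD, with no pretence of modelling 16S
divergence.

**What the generator does not emulate.** Taxonomic structure, phylogenetic
signal in abundances, compositional negative correlation bias at low
richness, batch effects, and the mutual coupling between community
composition and soil chemistry (in the generator the community latent is a
node in the path model, not a summary of the count table). Passing
recovery tests therefore certifies the algorithms, not the biology of any
particular field system.

**Default scale.** Tests and examples run at 40–150 taxa and 18–60
samples; the full field-scale configuration (thousands of taxa) is valid
but slow, and nothing in the code depends on scale.

# Diversity

Rarefaction subsamples each sample without replacement (multivariate
hypergeometric) to a common depth, one recorded draw per sample. Alpha
diversity reports observed richness; bias-corrected Chao1
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$, defined even when doubletons are
absent; Shannon entropy with natural logarithms (the convention matters
only when comparing against tools using log base 2); Simpson concentration
$\sum p_i^2$ with its inverse; and Faith's PD as the branch length of the
rooted subtree spanning the present taxa, root path included (unrooted
conventions differ; ours is stated so cross-tool comparisons are
interpretable). All-zero samples yield `NA`, never 0 — an undefined index
is not a minimal one. Whether alpha diversity should use rarefied or raw
counts is genuinely open in practice; the pipeline default is rarefied,
and `alpha_diversity()` accepts either.

Beta diversity uses Bray–Curtis dissimilarity on rarefied counts, PCoA by
Gower double-centering with coordinates scaled by the square root of each
positive eigenvalue, and a one-way PERMANOVA implemented from first
principles (sums of squared distances partitioned by group, pseudo-F,
label permutation). Numerical choices worth stating: negative PCoA
eigenvalues (non-Euclidean input) are excluded from the
proportion-explained denominator, with a Cailliez correction available by
flag; the permutation p-value uses the $(1 + \#\{F^* \ge F\})/(1 + B)$
convention and so never returns 0; and permutations that merely relabel
an identical partition reproduce the observed F exactly, so even perfectly
separated groups have a p-value floor set by the partition probability —
with two groups of six, that floor is what a careful reader should expect,
not $1/(B+1)$.

# Co-occurrence networks

Networks are built per treatment group by default (replicate plots are the
observations; pooling across treatments would conflate treatment effects
with associations), with a pooled mode available. After an optional
prevalence/abundance filter — and the mandatory removal of zero-variance
taxa, for which Spearman correlation is undefined — all taxon pairs are
correlated by Spearman's rank correlation (mid-ranks for ties), two-sided
p-values from the t approximation, and Benjamini–Hochberg adjustment
applied jointly across all upper-triangle pairs (the conservative,
standard scope). An edge requires, strictly, $|\rho| > 0.8$ **and**
adjusted $p < 0.05$; both thresholds are parameters and both are recorded
on the network object. With six replicates per group the t-approximate
p-values are coarse — the smallest achievable two-sided p at $n = 6$ is
about 0.003 before adjustment — so at the study's own scale the edge rule
is dominated by the correlation threshold. This is a property of the
design, not of the implementation, and is the main reason the recovery
experiments below use more samples.

Topology metrics are computed on the unweighted simple graph, signs kept
as attributes: node/edge counts split by sign, average degree $2E/N$,
density $2E/(N(N-1))$, mean local clustering (degree-<2 nodes count 0),
average path length and diameter as unweighted hop counts on the largest
connected component (reported alongside the component count), and Newman
modularity of the best Louvain partition over 10 seeded restarts at
resolution 1. Hop-count path lengths are necessarily $\ge 1$; because some
published tables print sub-1 "path lengths" under an unstated
normalisation, `*_per_node` diagnostic columns (metric divided by $N$) are
also emitted, but the standard definitions are the ones reported.
Modularity change between treatments is summarised as an integer percent
reduction relative to the reference network.

# Stability

**Cohesion.** Pairwise Pearson correlations of per-sample relative
abundances (Pearson, not Spearman: the cohesion literature's convention,
and a different computation from edge inference serving a different
purpose). Under the default `taxa_shuffle` null model each taxon's vector
is permuted across samples `n_null` times and the mean null correlation is
subtracted pairwise. A taxon's positive (negative) connectedness is the
mean of its strictly positive (negative) corrected correlations; sample
cohesion weights connectedness by relative abundance. Note an honest
statistical caveat: for truly independent taxa the corrected correlations
are centred noise, so the positive-part mean is small but positive of
order $1/\sqrt{n_{samples}}$ — cohesion shrinks toward zero with sample
count but is not unbiased at zero. The `none` null model makes every step
exactly hand-checkable and is what the worked-example tests use. Taxa
whose *relative abundance* is constant are excluded (a count-constant
taxon need not be, and vice versa). The stability index is the ratio of
absolute negative to positive cohesion, per sample and as a group mean
with standard error; it is invariant to rescaling any sample's library
size, as a compositional statistic must be.

**Robustness.** For each removal fraction, nodes are deleted uniformly at
random or highest-degree-first (ties broken randomly), and the statistic
is the fraction of surviving nodes that retain at least one edge — the
plainest reading of "changes in connectivity". The full curve over
fractions 0–0.95 is emitted with mean ± SD over repetitions, and the value
at 50% removal is the headline number, covering both the single-point and
whole-curve readings of the protocol. Alternative statistics
(giant-component fraction and the like) were considered and deliberately
not multiplied: one dialect, stated, beats a menu.

**Vulnerability and complexity.** Global efficiency is the mean inverse
shortest-path length over all node pairs (0 for disconnected pairs) on the
full node set; vulnerability is the largest relative efficiency drop from
deleting a single node. Complexity is reported as average degree (linkage
density) — the standard complexity proxy in this literature and already a
topology column; where a figure's "complexity" is otherwise undefined,
this is the interpretive choice made, and it is stated rather than hidden.

# PLS path modelling

The path model is estimated by the classical Lohmöller iteration:
standardise manifests, start outer weights equal, alternate inner proxies
(path weighting by default; centroid and factorial available) with outer
updates (mode A correlations by default, mode B regressions), rescale
scores to unit variance, and stop when the largest outer-weight change
falls below $10^{-7}$. Path coefficients are then OLS regressions of each
endogenous latent score on its predecessors, $GoF =
\sqrt{\overline{communality}\cdot\overline{R^2}}$, and sign indeterminacy
is resolved by forcing each latent to correlate positively with its first
manifest — making the fit deterministic and invariant to sample order.
Bootstrap intervals resample rows with replacement; a path is flagged
significant when its 95% percentile interval excludes zero; resamples
that make a manifest constant are skipped and counted. Missing data are
handled by listwise deletion only — at the field design's $n = 18$,
imputation would be invention. With few, noisy manifests per block,
composite scores attenuate path estimates slightly (the recovery
experiments show mean bias under 0.05 at $n \approx 500$, concentrated in
the two-manifest blocks); with a single manifest per block the estimator
collapses exactly to standardised OLS path analysis, which the tests
exploit as an oracle.

# Recovery experiments and their settings

Two experiments tie the whole pipeline back to planted truth. Module
recovery generates communities at latent `rho_in = 0.9`, `rho_out = 0`,
45 samples, builds the network, and compares the Louvain partition with
the planted modules by adjusted Rand index (mean over 10 seeds; observed
means are ≈0.99). The network threshold for this experiment is
`rho_min = 0.6`, chosen a priori: negative-binomial sampling attenuates
observed rank correlations well below the latent 0.9, and the experiment
specifies the generator regime, not the publication threshold. Path
recovery fits the four-block model at $n \approx 500$ and checks all
coefficients against the generator's, with the attenuation caveat above.

Simulation sizes throughout (1,000 null datasets with 199 permutations
for PERMANOVA calibration; 100 repeats × 200 bootstrap resamples for the
significance calibration; 10 seeds for recovery) were chosen as the
smallest sizes at which the binomial/Monte-Carlo error of the checked
quantity is comfortably inside the acceptance band, and they are the
package's own test conditions, stated here so they can be reproduced or
scaled up.

# Known limitations

- Spearman thresholding ignores compositionality; at desk scale with
  planted modules it is adequate, on real data tools like SparCC or
  SPIEC-EASI address a bias this package does not.
- With 6 replicates per network, every edge p-value is coarse; treat
  per-group networks at that scale as descriptive.
- The robustness statistic is one of several defensible connectivity
  readings; curves using other statistics are not comparable number-for-
  number.
- PLS-PM is a composite-based approximation to structural equation
  modelling; covariance-based ML estimation (lavaan-style) is out of
  scope, as are model-fit chi-square statistics.
- The generator's treatment effects are free parameters, not calibrated
  to any published effect table.
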
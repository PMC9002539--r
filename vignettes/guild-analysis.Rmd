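---
title: "Paired-design guild analysis of the oral microbiome: models and methods"
author: "OralGuilds authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-design guild analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OralGuilds)
```

## The analysis this package implements

OralGuilds implements the statistical pipeline of a paired-design oral
microbiome intervention study: two phenotype groups of subjects (PROP
non-tasters, NT, and super-tasters, ST, classified from labeled-magnitude-
scale ratings of a PROP-impregnated paper disk), each sampled before and
after an oral-rinse intervention, with 16S ASV counts, a rooted phylogeny,
salivary-protein measurements and sensory ratings per sample. The stages
are:

1. rarefaction and alpha diversity (observed ASVs, Shannon, Pielou evenness,
   Faith's PD),
2. weighted and unweighted UniFrac, PCoA and covariate-adjusted PCoA,
3. PERMANOVA with free and subject-stratified (restricted) permutations,
4. co-abundance **guild** construction from repeated-measures correlations,
5. guild–phenotype association by linear mixed models with BH FDR control,
6. tripartite guild/protein/sensory correlation networks, one per taster
   group.

Because the phenotype tables of such studies are typically not public, the
package ships a synthetic-data generator that emulates the full study
structure with planted ground truth, so every stage is testable end to end.

```{r quick, eval = FALSE}
cfg <- parseConfig(NULL)      # defaults: simulate the default scenario
cfg$out_dir <- "demo_run"
report <- runPipeline(cfg)
```

## Models and estimators

### Phylogenetic diversity and UniFrac

Both UniFrac variants and Faith's PD are computed from one post-order pass
that accumulates, per branch, the fraction of each sample's reads descending
from that branch. For samples $A,B$ and branches $b$ with lengths $\ell_b$
and descending mass fractions $p_A(b)$:

* unweighted: $\sum_b \ell_b\,[p_A(b)>0 \oplus p_B(b)>0] \,/\,
  \sum_b \ell_b\,[p_A(b)>0 \lor p_B(b)>0]$ — presence/absence only;
* weighted (raw, the default): $\sum_b \ell_b\,|p_A(b)-p_B(b)|$; the
  `normalized` flag divides by $\sum_b \ell_b\,(p_A(b)+p_B(b))$. The raw
  form is the default because conventions differ across pipelines and the
  raw form is the one the normalised form is derived from;
* Faith's PD: $\sum_b \ell_b\,[p(b)>0]$, which by construction includes the
  path to the root (the rooted convention — stated explicitly because both
  conventions are in circulation). PD is therefore monotone under adding
  taxa and equals the total tree length when all tips are present.

Shannon diversity uses log base 2 (bits) by default, configurable; evenness
is Pielou's $J = H/\log_2 S$, defined as 0 at richness 1. Rarefaction
subsamples without replacement; samples below the target depth are dropped
(not padded), with a warning.

### Ordination and inference

PCoA Gower-centers $-\tfrac12 J D^2 J$ and eigendecomposes; coordinates are
eigenvectors scaled by $\sqrt{\lambda}$ for positive eigenvalues, negative
eigenvalues are reported but produce no axis, and explained proportions are
taken over the positive-eigenvalue sum only (the negative mass is reported
separately). Adjusted PCoA projects the Gower matrix onto the orthogonal
complement of a covariate design matrix ($H G H$ with
$H = I - X(X^\top X)^{-1}X^\top$) before eigendecomposition — with subject
indicators as covariates this removes stable inter-individual differences,
the dominant source of variation in paired microbiome designs.

PERMANOVA uses the standard distance-based decomposition and the add-one
permutation p-value, so $p \ge 1/(n_{perm}+1)$. Two permutation schemes
cover the study's contrasts:

* **free** — labels permuted across samples; used for NT-vs-ST at a single
  timepoint, where each subject contributes one sample and subjects are the
  exchangeable unit;
* **stratified_by_subject** — timepoint labels permuted within each subject;
  the exchangeability structure of the paired pre/post contrast
  ("individual-stratified"). Single-sample strata are held fixed.

The paired/unpaired univariate tests (Wilcoxon signed-rank, Mann–Whitney,
Friedman) follow base R, with one refinement: for $n \le 12$ non-zero paired
differences the signed-rank p-value is computed by exact sign-flip
enumeration with average ranks, which stays exact under ties where the
standard implementation falls back to a normal approximation. Zero
differences are dropped (Wilcoxon's original rule) and counted.

### Repeated-measures correlation

ASV–ASV and phenotype correlations across repeated samples of the same
subjects use the Bland–Altman within-subject estimator: both variables are
centered by subject means, $r$ is the Pearson correlation of the pooled
residuals, $df = N - k - 1$ for $N$ observations on $k$ subjects, and the
p-value comes from the t distribution. Per-subject offsets cancel exactly
(a property the test suite checks to $10^{-12}$). With the study geometry
(39 samples, 20 subjects) $df = 18$, which matters below.

### Guild construction

Guilds are built on the prevalent ASVs — those present in strictly more
than half of the samples — from arcsine-square-root transformed whole-
community proportions:

1. all pairwise repeated-measures correlations $r_{ij}$;
2. distance $d = (1-r)/2$, so anticorrelated ASVs are maximally distant;
3. average-linkage agglomerative tree;
4. dichotomic top-down traversal: a node is accepted as a guild when the
   *minimum* pairwise $r$ among its members exceeds a threshold, otherwise
   it splits into its two children and the traversal recurses;
5. accepted nodes smaller than `minGuildSize` (default 2) go to the
   unassigned set; guilds are numbered by descending summed abundance.

**The acceptance threshold.** The default threshold is the critical
correlation for two-tailed significance at $\alpha = 0.05$,
$r_{crit} = t_{1-\alpha/2,df}/\sqrt{df + t^2}$ ($\approx 0.44$ at
$df = 18$): every pair inside an accepted guild must be individually
significantly co-abundant. This choice is deliberate and load-bearing. With
small repeated-measures df the null sd of $\hat r$ is $1/\sqrt{df} \approx
0.24$, and simulations with planted guild structure show that a lax
threshold (e.g. 0) accepts tree nodes whose minimum pairwise $r$ is pure
estimation noise, merging unrelated guilds. Compositionality makes this
worse: when one guild carries a large or strongly shifted share of the
community, its fluctuations enter every other taxon's proportions through
the denominator, inducing a spurious *positive* correlation
($\approx +0.09$ in the default scenario) between unrelated guilds. The
significance rule rejects both noise sources, is parameter-free, and adapts
to study size; at the default scenario it recovers a median of 13 of 13
planted guilds with median adjusted Rand index 1.0 over 25 replicates.
Pass `rThreshold = 0` to reproduce the laxest variant.

Guild abundance per sample is the arcsine-square-root of the *sum of
untransformed member proportions* — the transform of the guild's total
community share, not a sum of transformed values.

### Associations and networks

For each (guild, variable) pair the package fits

$$\operatorname{asin}\sqrt{\text{guild share}} \sim \text{variable} +
\text{age} + \text{gender} + \text{bmi} + (1\,|\,\text{subject})$$

by REML (nlme), with age and BMI standardised and gender as a binary
indicator; covariates that are constant or collinear within the fitted
subset are dropped with a warning rather than crashing the batch.
Benjamini–Hochberg adjustment runs within each data-type family
(guild–protein, guild–sensory, protein–sensory, guild–guild) because the
edge families answer different questions; a `globalFamily` flag pools them.
Networks retain edges with $q$ strictly below 0.25 — the conventional
exploratory FDR level for correlation screens of this kind — include only
nodes with degree $\ge 1$ (flag to keep all), and mark guild–guild edges
"dashed", all others "solid", with signs from the coefficient or
correlation.

## The synthetic scenario

`syntheticScenario()` encodes the study conditions: 10 NT + 10 ST subjects,
two timepoints, one ST post-intervention sample missing (39 samples), 300
ASVs of which 60 are prevalent and partitioned into 13 guilds, multinomial
counts at 5,000 reads/sample (a desk-scale depth; the field-scale 76,000 is
a config value for real data). Per sample, each guild carries a latent
factor $f_{g,s} \sim N(\mu_{g,s} + u_{g,\text{subject}}, 1)$ with subject
offsets $u$ (sd 0.5); prevalent ASV $i$ has log abundance
$base_i + \lambda_i f_{guild(i),s} + \varepsilon$ with loadings
$\lambda_i \sim U[0.5, 1]$ and ASV noise sd 0.3. Non-prevalent ASVs get a
low-median, high-dispersion tail (base $N(-8,1)$, per-sample log noise sd
2) so that they stay below 50% prevalence; the prevalent set carries the
large majority of reads. Planted effects:

* one guild's factor mean is shifted in all ST samples (baseline group
  difference);
* another guild's factor mean is shifted only in NT post-intervention
  samples (the NT-specific intervention response);
* protein and sensory variables are subject random intercepts plus noise;
  two proteins fall and two rise post-intervention; nine protein variables
  are coupled to guild factors in ST subjects against one protein and one
  sensory coupling in NT — producing the ST-denser network pattern.

**Effect sizes.** The planted factor shifts default to 2.5 (log scale,
against factor sd 1). This was set by a design-stage power analysis: the
generator's stated purpose is that planted effects are detectable at 10
subjects per group, and with 13 independent guild dimensions diluting the
multivariate signal, weighted-UniFrac PERMANOVA power at a shift of 0.8 is
only ~0.16 (baseline contrast) and ~0.08 (stratified intervention
contrast); at 2.5 both reach ~0.84. A shift of 2.5 corresponds to roughly a
five-fold change in the guild's expected share — large, but comparable to
the taxon-level differences such studies report as significant. The
protein–guild coupling (2.0) was sized the same way so a planted link is
recovered through the mixed-model + BH route in ~80% of replicates.

The pipeline's four PERMANOVA contrasts run on **weighted** UniFrac by
default: the generator plants abundance shifts in prevalent guilds, which
presence/absence UniFrac cannot see by construction (every prevalent ASV is
present nearly everywhere). Unweighted UniFrac is still computed and
written, and the choice is a config field (`distance`).

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: taxonomic structure (guilds are independent
of the phylogeny by default), overdispersion beyond multinomial sampling,
sample-to-sample depth variation, batch effects, and the possibility that
real guilds overlap or change membership across conditions. The generator
validates the machinery, not the biology.

## Numerical choices and degenerate inputs

* Distance matrices must be symmetric to $10^{-8}$ with zero diagonal;
  eigenvalues within $|\lambda_{max}| \cdot 10^{-10}$ of zero are treated
  as zero.
* PERMANOVA permutation F comparisons use a $10^{-12}$ slack so ties with
  the observed statistic count as exceedances (conservative).
* `rarefy` is deterministic given its seed; samples are processed in row
  order.
* Constant ASVs (zero residual variance) are unassigned, not errors;
  all-zero paired differences give p = 1 with a warning; empty networks are
  valid results.
* Ties at equal merge heights in the clustering tree follow
  `stats::hclust` order (lower index first), making assignments
  reproducible under input-order permutation (checked by test).

## Problem sizes used by the test suite

The suite validates calibration at desk scale: PERMANOVA type-I error over
2,000 null datasets (12 samples, 199 permutations each) against the 95%
binomial band around 0.05; FDR calibration over ~2,000 null mixed-model
fits; guild recovery over 20 scenario replicates plus an 8-replicate
loading sweep for monotonicity; oracle equivalence of UniFrac/PD on 50
random 8-tip trees against a per-branch brute-force implementation, with
`picante` and `vegan` as independent cross-checks where they overlap.

## Known limitations

* The guild construction assumes a hard partition; overlapping or nested
  co-abundance structure is approximated by whichever node the traversal
  accepts first.
* The LMM route reports the variable's slope on the transformed-share
  scale; effect sizes are not back-transformed.
* The repeated-measures correlation assumes a common within-subject slope
  across subjects (the Bland–Altman model); heterogeneous per-subject
  correlations are averaged, not modelled.
* With only two timepoints, the subject-stratified PERMANOVA has $2^k$
  distinct relabelings; with very few complete pairs the attainable p-value
  floor is coarse.
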
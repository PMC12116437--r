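---
title: "Models and design choices in cfosnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in cfosnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cfosnet` turns regional c-Fos⁺ cell counts from a two-group rodent
study into (i) per-region and per-network activation statistics and
(ii) group-wise functional connectomes with hub classification. This
vignette explains the models, the tunable parameters, the synthetic
generator, and the places where the design was genuinely open —
together with what our validation experiments do and do not show.

## From counts to densities

The raw observation is one count per (subject, region, hemisphere,
slide) with its ROI area in mm². `compute_density()` pools the two
hemisphere counts of a slide and divides by the pooled area, then
averages slide densities within a region. We deliberately use the
*mean of slide densities* rather than pooled counts over pooled area:
the two differ when slide areas differ, and mean-of-densities is the
aggregation that treats each slide as one measurement of the same
underlying density. Unilateral records are allowed (midline nuclei
such as the interpeduncular nucleus are not bilateral) and use the
available hemisphere. A subject with no record for a region yields an
explicit `NA`, which downstream correlation handles by
pairwise-complete observations — never a silent zero, which would
fabricate an activation value.

## The activation model

Counts are overdispersed relative to Poisson (biological variation in
activation between animals exceeds counting noise), and littermates
share prenatal environment, so the per-region model is a
negative-binomial mixed model:

$$\text{count}_{i} \sim \mathrm{NB}(\mu_i, \theta), \quad
\log \mu_i = \beta_0 + \beta_1\,\text{treated}_i + b_{\ell(i)} +
\log(\text{area}_i), \quad b_\ell \sim N(0, \sigma_\ell^2)$$

with variance $\mu + \mu^2/\theta$ (this mean/dispersion
parameterization is used consistently in the fitter *and* the
generator). The log-area offset makes $\beta_1$ a log fold change on
*density*. Fitting uses the Laplace-approximated marginal likelihood
(glmmTMB); the treatment term is tested by a likelihood-ratio $\chi^2$
with 1 df — not a Wald test — and Holm's step-down adjustment controls
the family-wise error across the analyzed regions, taken as one
family. A Benjamini–Hochberg switch exists for users who prefer FDR
control. Cohen's d (pooled-SD, on subject densities) is computed for
regions in the screening band $0.05 < p < 0.1$ to flag
near-significant effects with large standardized size.

With one aggregated observation per subject and region, a
subject-level random intercept is not identifiable separately from the
NB dispersion, so region models omit it; the pooled *network* models
(all subject × region observations of an a-priori region set, region
fixed covariate) retain a subject random intercept because subjects
contribute several observations there.

## The functional connectome

Within each group, Pearson correlations between regional density
profiles are computed across subjects (pairwise-complete, minimum 3
complete pairs), with p-values from the t transform with per-pair
degrees of freedom. We store a *signed* R² $= \mathrm{sign}(r)\,r^2$:
thresholding compares magnitudes, so strong negative couplings form
(negative-signed) edges rather than being discarded, and the sign
survives as an edge attribute.

Candidate edges are first restricted to anatomically connected pairs
(a user-supplied binary adjacency standing in for an axonal
connectome; a directed source is OR-symmetrized). This masking is what
suppresses correlations mediated by unobserved common input rather
than direct interaction. Edges then require $|R^2| > 0.7$ *and*
$p < 0.05$, both strict, so ties at exactly the threshold are
excluded. No multiplicity correction is applied across the 630 pair
tests at this stage — the screening is deliberately descriptive, and
the dual threshold is the filter; this is logged prominently rather
than hidden.

Whether anatomically connected pairs really correlate more strongly is
itself testable: `compare_connected_unconnected()` runs a Welch t-test
of the pairwise r values (r by default; signed R² or |r| by config)
between connected and unconnected pairs, treating pairs as
observations. Pairs sharing a region are not independent, so the
nominal df overstate the information content; we report the test as a
descriptive diagnostic, which is also why the shuffled-adjacency null
experiment (below) matters.

## Centralities and hubs

Degree and betweenness are computed on the unweighted, undirected
graph, ignoring edge signs. Betweenness sums, over unordered pairs of
distinct nodes, the fraction of shortest paths through the candidate
node; unreachable pairs contribute zero. The unordered-pair
normalization (each pair counted once) is fixed for reproducibility;
it cannot affect quantile-based hub calls, which are scale-free.

Hubs: a region is a hub iff it is strictly above the 80% quantile
(linear-interpolation quantiles, R type 7) in *both* degree and
betweenness. A sum-based alternative — rescale both centralities to
[0, 1], sum, threshold the sum at its own 80% quantile — is available
behind `hub_rule = "sum"`. The conjunctive per-measure rule is the
default because it is the rule that downstream interpretation actually
uses (a hub must be highly connected *and* a bridge); with strict
exceedance, all-equal centralities correctly yield an empty hub set.
Group degree distributions are compared by a Mann–Whitney rank-sum
test with tie-corrected normal approximation.

## The synthetic generator

`generate_study()` emulates the generative structure the analysis
assumes:

* two groups (defaults 10 vs 11 subjects) with treatment assigned at
  the **litter** level — prenatal exposure acts on the dam — and 14
  litters split proportionally between groups;
* a litter random intercept on the log-density scale (`litter_sd`,
  default 0.3);
* a latent multivariate-normal activation vector per subject with a
  per-group correlation matrix, entering the log mean scaled by
  `latent_scale` — a Gaussian-copula-like construction that keeps
  counts NB marginally while inducing controllable cross-region
  correlation;
* negative-binomial totals with mean $\mu \cdot$ total area
  (`nb_dispersion`, default 10; `Inf` gives Poisson), split
  multinomially with equal probabilities over hemisphere × slide
  records (hemisphere symmetry reflects the absence of
  inter-hemispheric differences in this design), conserving the total
  exactly;
* defaults: 36 regions spanning reward, social-behavior, stress,
  autism-associated and control panels; baseline 100 cells/mm²;
  per-hemisphere slide areas 0.12–1.5 mm²; two slides per region.

Because the study it emulates deposits no raw data, dispersion and
variance components are *not* calibrated to the original study; they
are realistic values fixed once (see the scenario notes below). What
passing tests show is therefore that the pipeline recovers structure
from data generated under its own assumptions at realistic noise
levels — not that real c-Fos data satisfy those assumptions. In
particular the generator does not emulate segmentation errors,
section damage/missingness patterns, or non-NB zero inflation.

## Validation scenarios and their design

Three canonical scenarios (in `scenarios.R`) are frozen package
constants, not tuning knobs:

* **Planted hub** (`scenario_hub_recovery`): latent correlation 0.9
  between the hub and every region, as one shared factor — which
  forces 0.81 between non-hub pairs, a mathematical consequence of
  positive semidefiniteness, not a choice. An a-priori design analysis
  showed that with this latent background, *any* appreciable density
  of non-hub anatomical edges floods the graph with spurious
  functional edges and produces co-hubs: with non-hub edge density
  0.05–0.3 the unique-hub recovery rate is only 3–17%. The anatomical
  mask is precisely what makes the planted hub identifiable, so the
  scenario uses the pure star connectome (`edge_density = 0` with a
  planted hub — an explicitly supported configuration). Noise
  parameters (latent scale 1.0, dispersion 20, litter SD 0.2, 0.5 mm²
  sections) keep log-scale counting noise small against unit latent
  signal. Recovery is scored per replicate as "the planted region is
  the *unique* hub in both group graphs".
* **Single region** (`scenario_single_region`): the calibration and
  recovery testbed for the region model (litter SD 0.3, dispersion 10,
  latent term off — with one region it would duplicate the dispersion).
* **Adjacency-coupled** (`scenario_adjacency_coupled`): latent
  correlation $I + \rho A$ supported only on anatomically connected
  pairs; $\rho$ is capped at $0.95/|\lambda_{\min}(A)|$ (≈ 0.15 at
  density 0.3) because that is the largest value for which such a
  matrix can be positive definite at all. Low counting noise isolates
  the anatomical structure.

## Numerical choices and degenerate inputs

* Optimizer: glmmTMB/nlminb on the Laplace objective, up to 500
  iterations; fits that fail convergence or a positive-definite
  Hessian raise a labeled error carrying the region name. All-zero
  counts in one group return a flagged degenerate result instead of a
  spurious fit.
* LR statistics are floored at 0 (numerically tiny negative deviances
  become exact zeros).
* Zero-variance regions get NA correlation rows with a warning; pairs
  with fewer than 3 complete observations are NA.
* The paired Wilcoxon signed-rank uses average ranks, tie-corrected
  variance and no continuity correction, returning a signed Z;
  all-zero differences give a flagged degenerate result.
* Writers emit CSV with shortest-round-trip decimal representations
  (up to 17 significant digits), so write → read reproduces doubles
  bit for bit; the pipeline is deterministic given its inputs, and the
  run manifest records inputs, settings, seed and versions.

## Known limitations

* **Small-sample calibration of the LR test.** With treatment assigned
  at the litter level and only 14 litters, the 1-df likelihood-ratio
  test is measurably anticonservative at study scale: our null
  simulations at the default conditions give an empirical type-I rate
  near 0.075 at nominal 0.05 (with no litter effect at all it is
  ≈ 0.064). This matches the classic denominator-degrees-of-freedom
  argument — the treatment contrast is effectively estimated on ~12
  between-litter degrees of freedom, and $P(|t_{12}| > 1.96) \approx
  0.072$. The implementation reports the LR test as specified; a
  parametric-bootstrap LRT or Satterthwaite-type correction would
  restore calibration at the cost of either runtime or leaving the
  LR framework, and users drawing confirmatory conclusions at these
  cluster counts should be aware of the inflation. We chose to keep
  the realistic litter effect in the null scenario rather than
  simulate an unrealistically clean design that would hide this
  property.
* The connected-vs-unconnected t-test treats region pairs as
  independent observations; its p-values are descriptive.
* Betweenness on graphs with many tied shortest paths depends only on
  path counts, not weights; edge weights (|signed R²|) are carried as
  attributes but never used in centralities, mirroring the unweighted
  analysis the pipeline implements.
* Problem sizes used by the validation experiments (200 oracle
  graphs, 100 hub replicates, 1000 null fits, 500 recovery fits, 200
  coupling replicates) were chosen to make simulation error small
  relative to the properties being checked while keeping a full
  validation run in the minutes range on one core.
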
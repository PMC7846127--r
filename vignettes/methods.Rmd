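---
title: "Kinship and F_ST estimation under arbitrary population structure: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship and F_ST estimation under arbitrary population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The parameters

All quantities in `kinfst` are identity-by-descent (IBD) probabilities
relative to an explicit ancestral reference population $T$. The kinship
coefficient $\varphi_{jk}^T$ is the probability that one allele drawn at
random from individual $j$ and one from individual $k$, at a random locus,
descend from a single ancestral allele in $T$; the inbreeding coefficient
$f_j^T$ is the same probability for the two alleles of one individual, and
self-kinship satisfies $\varphi_{jj}^T = (1 + f_j^T)/2$. Wright's
multiplicative partition separates total inbreeding into a *local*
(family) component $f_j^{L_j}$, relative to the most recent subpopulation
$L_j$ an individual drew its alleles from, and a *structural* component
$f_{L_j}^T$:

$$(1 - f_j^T) = (1 - f_j^{L_j})(1 - f_{L_j}^T),$$

implemented by `wright_partition()`, which solves for the structural part.
The generalized $F_{ST}$ of $n$ individuals is the weighted mean of their
structural inbreeding coefficients,
$F_{ST} = \sum_j w_j f_{L_j}^T$ with $w_j \ge 0$, $\sum_j w_j = 1$
(`generalized_fst()`). Weights exist to undo sampling imbalance: with $K$
subpopulations weighted equally ($w_j = 1/(K r_u)$ for individuals in a
subpopulation of size $r_u$) the definition reduces to the familiar mean
per-subpopulation $F_{ST}$; in scenarios without discrete subpopulations
we default to uniform weights.

Two model layers connect these parameters to data. Under the *kinship
model*, genotype dosages $x_{ij} \in \{0,1,2\}$ at locus $i$ satisfy

$$E[x_{ij} \mid T] = 2 p_i^T, \qquad
  \mathrm{Cov}(x_{ij}, x_{ik} \mid T) = 4 p_i^T (1 - p_i^T)\varphi_{jk}^T,$$

with $p_i^T$ the ancestral allele frequency. Under the *coancestry model*,
latent individual-specific allele frequencies (IAFs) $\pi_{ij}$ satisfy
the analogous moments with coancestry coefficients $\theta_{jk}^T$, and
genotypes are $\mathrm{Binomial}(2, \pi_{ij})$ draws. The two connect via
$\theta_{jk}^T = \varphi_{jk}^T$ for $j \ne k$ and
$\theta_{jj}^T = f_j^T$: a coancestry matrix and a kinship matrix differ
only in their diagonal scale. `relatedness_matrix()` carries this
distinction as a `form` attribute and `convert_relatedness()` maps
between the forms (an involution). Because the coancestry model draws the
two alleles of an individual independently given its IAF, individuals
under it are always locally outbred, and $F_{ST} = \sum_j w_j
\theta_{jj}^T$. All simulations in this package are locally outbred, so
this identity holds for their true parameters.

True parameters live in $[0,1]$; *estimates* may legitimately fall outside
(the standard estimator produces negative kinship under structure), so
range checking is opt-in (`check_range`).

# Why the standard estimators fail under structure

All classical estimators here are ratio estimators. We follow the
*ratio-of-means* discipline throughout: per-locus numerator and
denominator terms are summed across loci before one division, which
converges almost surely to the ratio of expectations as independent loci
accumulate, with expectation error of order $1/m$. *Mean-of-ratios*
averaging of per-locus ratios, although prevalent for kinship in the
literature, has no such guarantee; the package implements it
(`kinship_std(form = "mean_of_ratios")`) purely as a comparison arm.

The standard kinship estimator centers genotypes with weighted allele
frequency estimates $\hat p_i = \frac{1}{2}\sum_j w_j x_{ij}$ and
normalizes by $4\sum_i \hat p_i(1 - \hat p_i)$. Its failure mode under
structure is precise and instructive: $\hat p_i$ is unbiased but *not*
consistent — its variance is $p_i(1-p_i)\bar\varphi^T$, where
$\bar\varphi^T$ is the weighted mean kinship, which does not vanish for
structured samples however large $n$ gets. The estimator therefore
converges to a doubly-centered distortion,

$$\hat\varphi_{jk}^{std} \to
  \frac{\varphi_{jk}^T - \bar\varphi_j^T - \bar\varphi_k^T + \bar\varphi^T}
       {1 - \bar\varphi^T},$$

whose bias differs per pair (`limit_kinship_std()`). The plug-in $F_{ST}$
inherits a uniform version of this bias,
$(F_{ST} - \bar\varphi^T)/(1 - \bar\varphi^T)$, conveniently
parameterized by the *bias coefficient*
$s^T = \bar\theta^T / F_{ST} \in (0, 1]$ (`bias_coefficient()`): the
relative error of the plug-in estimator approaches $s^T$ when
$F_{ST} \ll 1$. Independent subpopulations give $s^T = 1/K$, which is why
these biases went largely unnoticed under the classical model; a fully
admixed population can push $s^T$ toward 1 and the estimate toward zero.
The estimators for independent subpopulations (Weir-Cockerham, Weir-Hill,
Hudson/HudsonK, and the infinite-sample form they all reduce to) converge
analogously to $(F_{ST} - \tilde\theta)/(1 - \tilde\theta)$ with
$\tilde\theta$ the mean between-group coancestry
(`limit_fst_indep()`). These limits, not the estimators, are what the
`limit_*` functions compute; they take true parameters only and serve as
oracles in the test suite.

# The consistent estimator

The pairwise statistic

$$A_{jk} = \frac{1}{m}\sum_{i=1}^m (x_{ij} - 1)(x_{ik} - 1) - 1, \qquad
  E[A_{jk}\mid T] = (\varphi_{jk}^T - 1)\, v_m^T,$$

with $v_m^T = \frac{4}{m}\sum_i p_i^T(1-p_i^T)$, shifts all the bias into
a *single shared scale* — in contrast to the $n$ pair-dependent nuisance
terms of the standard estimator. Dosage algebra bounds every entry in
$[-2, 0]$. If the least-related pair of individuals in the data has zero
kinship — which defines $T$ as their most recent common ancestor
population — then the minimum expected $A_{jk}$ equals $-v^T$, and

$$\hat\varphi_{jk}^{new} = 1 - A_{jk}/\hat A_{\min}$$

is consistent. The package's $\hat A_{\min}$ is the proof-of-principle
subpopulation version: the minimum over unordered pairs of distinct
groups of the unweighted between-group mean of $A_{jk}$
(`a_min_subpops()`). The groups need not be independent or unstructured;
only the least related pair must be unrelated. Ties in the minimum are
value-identical, so no tie-break rule is needed; between-group means use
equal weight per individual pair, following the plain average in the
estimator's definition. The companion Weir-Goudet estimator replaces the
minimum with the overall pair *average* and therefore targets
$(\varphi_{jk} - \tilde\varphi)/(1 - \tilde\varphi)$ rather than the IBD
probability (`kinship_wg()`, `limit_kinship_wg()`); both are provided so
the difference is directly computable.

# The simulator

Two generative models with fully known parameters validate the
estimators. Both use $K = 10$ (intermediate) subpopulations with
differentiation on a linear gradient $f_{S_u}^T = u\tau/K$ — a serial
founder effect — ancestral frequencies drawn uniformly on $(0.01, 0.5)$,
Balding-Nichols subpopulation frequencies
$\mathrm{Beta}(p(1/f - 1), (1-p)(1/f - 1))$, binomially drawn genotypes,
and independent loci (no linkage — real data will be noisier per
effective locus).

* **Independent subpopulations** (`simulate_indep()`): one-hot membership,
  random Dirichlet-rounded group sizes kept above $n/(3K)$ (tiny groups do
  not occur in real samples; the $\pm 1$ repair loop that restores the
  exact total can nudge one group a single count below the floor, which we
  accept as the printed procedure's behavior), balanced weights
  $w_j = 1/(K r_u)$. Closed form $\tau = 2 K F_{ST}/(K+1)$; the bias
  coefficient is exactly $1/K$.
* **1D-geography admixture** (`simulate_admix()`): subpopulations at
  coordinates $x_u = u$, individuals evenly spaced on the same range,
  ancestry proportional to a Normal$(0,\sigma)$ density of distance
  (random-walk spread), IAFs $\pi = P_{sub} Q^\top$, true coancestry
  $\Theta = Q\,\mathrm{diag}(f)\,Q^\top$. The spread $\sigma$ is the root
  of the bias-coefficient equation (bisection bracket $[0.01, 100]$, root
  tolerance $10^{-10}$; the function is smooth and monotone from $1/K$ to
  1 on this bracket, verified by scan), and $\tau$ then follows in closed
  form. The default conditions ($n = 1000$, $m = 3\times10^5$, $K = 10$,
  $F_{ST} = 0.1$, $s^T = 1/2$) give $\sigma \approx 1.78$ and $\tau
  \approx 0.901$; $s^T = 1/2$ is chosen to halve the standard plug-in
  estimate, a deliberately adversarial but human-plausible scenario
  ($F_{ST} = 0.1$ is comparable to between-continental-population
  estimates). Geographic clustering for subpopulation-based estimators
  assigns each individual to its nearest subpopulation, ties toward the
  lower index (the even grid never ties; robustness demands a rule).

What the simulator does *not* emulate: genetic linkage, genotyping error,
missingness, ascertainment beyond the uniform frequency window, and local
(family) inbreeding. Passing tests therefore demonstrate correctness of
the estimators under their stated model, not robustness to real-data
artifacts; with linkage the effective number of independent loci, and so
all Monte-Carlo errors, will be less favorable than $m$ suggests.

# Numerical and design choices

* **Orientation.** Matrices are loci × individuals, matching SNP-major
  plink storage and making blocked accumulation over loci natural.
* **Blocking.** All genotype estimators accumulate cross-products in
  row blocks (default 10,000 loci), capping transient doubles;
  `kinship_accuracy_admix()` generates blocks on the fly and never
  materializes the full matrices, so the $n=1000$, $m=3\times 10^5$ study
  fits comfortably in a few GB. Block boundaries provably do not affect
  results (tested against in-memory estimators at $10^{-12}$).
* **Missing data.** Not modeled by any of the estimators' derivations;
  estimators reject `NA` outright, and the reader offers an explicit
  complete-loci filter (`drop_missing_loci`), documented as an extension
  rather than silent behavior.
* **Fixed loci in mean-of-ratios.** Per-locus ratios
  $(x_{ij}-2\hat p_i)(x_{ik}-2\hat p_i)/(4\hat p_i(1-\hat p_i))$ are
  undefined at $\hat p_i \in \{0,1\}$; such loci are skipped and counted
  (`n_skipped` attribute). This skip rule is our choice — the
  mean-of-ratios family has no canonical published guard.
* **Weighted between-individual means.** The mean between coancestry
  $\tilde\theta$ is defined with uniform weights; for general weights we
  use the weighted off-diagonal analogue
  $(\bar\theta - \sum_j w_j^2\theta_{jj})/(1 - \sum_j w_j^2)$, which
  reduces exactly to the uniform expression. This generalization is our
  choice of convention, not a published definition. Relatedly, the
  independent-subpopulations limit uses the uniform-weight
  $\tilde\theta$ while the Weir-Goudet limit uses the unweighted pair
  mean $\tilde\varphi$; the two reductions are kept distinct on purpose.
* **RMSE convention.** `rmse_relative()` compares unique pairs $j<k$
  plus the diagonal on the *inbreeding* scale (kinship diagonals mapped by
  $2\varphi_{jj}-1$, the scale on which such matrices are plotted), and
  normalizes by the mean of the true coancestry-scale matrix. An
  off-diagonal-only flag is provided; with $n = 1000$ the diagonal
  carries 0.2% of the entries, so the convention barely moves the
  percentages.
* **Degenerate inputs.** Monomorphic-only data raise a zero-denominator
  error rather than returning NaN; $\hat A_{\min} \ge 0$ raises an error
  stating that unrelated-pair identification failed; a single individual
  at $n = 1$ is placed at the geographic midpoint; Normal-density
  underflow at tiny $\sigma$ falls back to the exact one-hot limit.
* **Tolerances.** Pure-parameter algebra (partition inversion, form
  round-trips, reference invariance) is tested at $10^{-10}$–$10^{-12}$
  relative; Monte-Carlo moment checks use 3-standard-error bands or
  explicitly generous bands where variance estimates converge slowly.

# Problem sizes used in the tests

The bundled suite exercises the full pipeline at reduced scales chosen to
keep the suite fast while preserving every qualitative conclusion:
estimator-accuracy orderings at $n = 1000$ with a tenth of the loci
($m = 30{,}000$; RMSE magnitudes scale roughly as $\sqrt{m}$, orderings
are unchanged), consistency grids at $n = 100$ over
$m \in \{10^3, 10^4, 10^5\}$, and 39-replicate prediction intervals
(order-statistic intervals: the range of 39 replicates is a 95% interval)
at $n = 100$, $m = 20{,}000$. The acceptance script runs the kinship
accuracy study at the full $n = 1000$, $m = 3\times 10^5$ scale.

# Known limitations

The subpopulation-based $\hat A_{\min}$ inherits the quality of the
partition: if the least related pair of groups has mean kinship well
above zero, all kinship estimates are biased downward proportionally, and
inspection of the estimates (or a better minimum estimator) is required.
Estimation of local inbreeding, needed for the generalized $F_{ST}$ when
individuals are not locally outbred, is out of scope — only the
closed-form pedigree values used in the worked examples are handled. The
Hudson pairwise estimator requires exactly two groups by construction.
Single-locus differentiation scans are outside the theory used here,
which is genuinely genome-wide: all convergence statements require many
independent loci.
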
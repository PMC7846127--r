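# kinfst

Kinship and F_ST estimation for arbitrary population structures.

## The problem

F_ST and kinship coefficients are identity-by-descent (IBD) probabilities
relative to an ancestral reference population T: the kinship coefficient
φ<sub>jk</sub><sup>T</sup> is the probability that random alleles drawn
from individuals j and k are IBD, the inbreeding coefficient
f<sub>j</sub><sup>T</sup> is its self version, and the generalized F_ST is
the weighted mean of per-individual *structural* inbreeding coefficients,

&nbsp;&nbsp;F_ST = Σ<sub>j</sub> w<sub>j</sub> f<sub>L_j</sub><sup>T</sup>,&nbsp;&nbsp;&nbsp;
(1 − f<sub>j</sub><sup>T</sup>) = (1 − f<sub>j</sub><sup>L_j</sup>)(1 − f<sub>L_j</sub><sup>T</sup>),

with non-negative weights summing to one. The estimators most used in
practice — the standard kinship estimator behind genetic relatedness
matrices, and the Weir-Cockerham, Weir-Hill, Hudson and related F_ST
estimators — are method-of-moments ratio estimators that are only
consistent under the independent subpopulations model. Under realistic
structure (admixture, relatedness between groups) they converge instead to
linearly-transformed or pair-distorted quantities and can underestimate
F_ST by a factor of two or more.

`kinfst` implements, for biallelic dosage data (loci × individuals, values
0/1/2):

* **A consistent kinship estimator.** The pairwise statistic
  A<sub>jk</sub> = mean<sub>i</sub>[(x<sub>ij</sub>−1)(x<sub>ik</sub>−1)] − 1
  has expectation (φ<sub>jk</sub><sup>T</sup> − 1)·v<sup>T</sup> with one
  shared nuisance scale v<sup>T</sup>, so a consistent estimate of its
  minimum — taken between the least-related pair of subpopulations, where
  kinship is zero and T becomes the MRCA population — unbiases the whole
  matrix: φ̂<sub>jk</sub> = 1 − A<sub>jk</sub>/Â<sub>min</sub>. Inbreeding
  and F_ST follow as 2φ̂<sub>jj</sub> − 1 and their weighted mean
  (`a_statistic()`, `a_min_subpops()`, `kinship_new()`, `fst_new()`).
* **The classical estimators it is compared against**: standard
  kinship/coancestry in ratio-of-means and mean-of-ratios forms,
  the three standard inbreeding variants, Weir-Cockerham, Weir-Hill,
  Hudson pairwise, HudsonK, Weir-Goudet for individuals, and the oracle
  bias adjustments (`fst_adjust_theta()`, `fst_adjust_s()`).
* **Closed-form asymptotic limits** of all of these under arbitrary
  coancestry (`limit_kinship_std()`, `limit_fst_indep()`,
  `limit_kinship_wg()`, ...), usable as oracles.
* **A calibrated simulator**: K independent subpopulations, and a
  1D-geography Balding-Nichols/admixture (BN-PSD) model whose spread and
  differentiation scale are solved so the bias coefficient
  s<sup>T</sup> = θ̄<sup>T</sup>/F_ST and F_ST hit chosen targets
  (`simulate_indep()`, `simulate_admix()`, `solve_sigma()`, `tau_admix()`).
* **I/O and a CLI**: plink BED/BIM/FAM and TSV readers/writers and the
  `inst/cli/kinfst` script with `simulate`, `kinship`, `fst`, `limits` and
  `evaluate` subcommands.

## Worked example

```r
library(kinfst)
set.seed(1)

# admixture along a 1D geography: n individuals, m loci, K intermediate
# subpopulations, F_ST = 0.1, bias coefficient s = 0.5
sim <- simulate_admix(n = 200, m = 50000, K = 10, fst = 0.1, s_target = 0.5)

# standard (GRM-style) plug-in F_ST is biased down by ~s
fst_std(sim$X)$value
#> [1] 0.05047767
limit_fst_std(0.1, s = 0.5) # its predicted limit
#> [1] 0.05263158

# the new estimator recovers the generalized F_ST
A <- a_statistic(sim$X)
K_new <- kinship_new(A, a_min_subpops(A, sim$labels))
fst_new(K_new)$value
#> [1] 0.09925405

# kinship matrix accuracy, in percent of the mean kinship
phi_true <- convert_relatedness(sim$theta, "kinship")
rmse_relative(K_new, phi_true, mean(sim$theta))
#> [1] 7.003843
rmse_relative(kinship_std(sim$X), phi_true, mean(sim$theta))
#> [1] 119.8411
```

The standard estimator's ~120% error is almost entirely its structural
bias (it converges to a doubly-centered transform of the kinship matrix);
the new estimator's error is Monte-Carlo noise that shrinks as loci
accumulate.

## Scope and conventions

Matrices are loci × individuals throughout. Estimators require complete
dosages; `read_genotypes(..., drop_missing_loci = TRUE)` provides an
explicit complete-loci filter. Multiallelic loci, polyploid dosages and
local-inbreeding inference (runs of homozygosity) are out of scope; the
vignette discusses the assumptions and limitations in detail.
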
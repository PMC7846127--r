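# Simulation models with known IBD parameters relative to the MRCA
# population: K independent subpopulations, and a 1D-geography admixture
# (Balding-Nichols intermediate frequencies combined through
# Pritchard-Stephens-Donnelly admixture proportions). Loci are simulated
# independently (no linkage). All randomness uses R's global RNG; pass
# `seed` to the high-level bundles for reproducibility.

#' Draw ancestral allele frequencies
#'
#' Independent uniform draws on `range` (default `(0.01, 0.5)`), avoiding
#' frequencies too close to fixation and mimicking an ascertained SNP panel
#' folded to the minor allele.
#'
#' @param m Number of loci.
#' @param range Lower/upper frequency bounds, inside `(0, 1)`.
#' @return Length-m vector of ancestral allele frequencies.
#' @export
draw_ancestral_freqs <- function(m, range = c(0.01, 0.5)) {
  if (!(0 < range[1] && range[1] < range[2] && range[2] < 1))
    stop("`range` must satisfy 0 < lo < hi < 1")
  stats::runif(m, range[1], range[2])
}

#' Draw subpopulation frequencies from the Balding-Nichols distribution
#'
#' Given ancestral frequencies p and a differentiation f, draws
#' \eqn{Beta(p(1/f - 1), (1-p)(1/f - 1))} per locus, which has mean p and
#' variance \eqn{f p (1 - p)} — the coancestry model for one subpopulation.
#' `f = 0` is the degenerate no-drift limit and returns p exactly.
#'
#' @param p_anc Length-m vector of ancestral allele frequencies.
#' @param f Differentiation (F_ST) of the subpopulation in `[0, 1)`.
#' @return Length-m vector of subpopulation allele frequencies.
#' @export
draw_bn_freqs <- function(p_anc, f) {
  if (f < 0 || f >= 1) stop("`f` must be in [0, 1)")
  if (f == 0) return(p_anc)
  nu <- 1 / f - 1
  stats::rbeta(length(p_anc), p_anc * nu, (1 - p_anc) * nu)
}

#' Per-subpopulation differentiation on a linear gradient
#'
#' The intermediate subpopulations have differentiation growing linearly
#' with their index, \eqn{f_{S_u}^T = u \tau / K}, modelling a serial
#' founder effect; \eqn{\tau \le 1} scales the overall F_ST.
#'
#' @param K Number of subpopulations.
#' @param tau Scale parameter in `(0, 1]`.
#' @return Length-K vector of differentiations.
#' @export
f_intermediate <- function(K, tau) {
  if (tau <= 0 || tau > 1) stop("`tau` must be in (0, 1]")
  (1:K) * tau / K
}

#' Differentiation scale for the independent-subpopulations model
#'
#' With the linear gradient [f_intermediate()], the equally-weighted F_ST is
#' \eqn{\tau (K + 1) / (2K)}, so the scale achieving a target F_ST is
#' \eqn{\tau = 2 K F_{ST} / (K + 1)} (about 0.18 for F_ST = 0.1, K = 10).
#'
#' @param fst_target Desired generalized F_ST in `(0, 1)`.
#' @param K Number of subpopulations.
#' @return The scale tau.
#' @export
tau_indep <- function(fst_target, K) {
  tau <- 2 * K * fst_target / (K + 1)
  if (tau > 1) stop("target F_ST infeasible: tau = ", signif(tau, 4), " > 1")
  tau
}

#' Random subpopulation sample sizes
#'
#' Dirichlet(1, ..., 1) proportions of n rounded to counts, redrawn until
#' every subpopulation has at least n/(3K) individuals (small subpopulations
#' do not occur in real data), then repaired to sum exactly to n by
#' repeatedly adding the sign of the deficit to a random entry.
#'
#' @param n Total number of individuals (`n >= 3K`).
#' @param K Number of subpopulations.
#' @return Length-K integer vector summing to n.
#' @export
random_subpop_sizes <- function(n, K) {
  if (K == 1) return(n)
  if (n < 3 * K) stop("need n >= 3K for the minimum-size constraint")
  repeat {
    x <- stats::rgamma(K, 1)
    r <- round(n * x / sum(x))
    if (min(r) >= n / (3 * K)) break
  }
  while ((delta <- n - sum(r)) != 0) {
    u <- sample.int(K, 1)
    r[u] <- r[u] + sign(delta)
  }
  as.integer(r)
}

#' Admixture proportions from a 1D geography
#'
#' Intermediate subpopulations sit at coordinates \eqn{x_u = u}; the n
#' individuals are spaced evenly at \eqn{y_j = 1/2 + (j-1) K / (n-1)}
#' (spanning 1/2 to K + 1/2; a single individual is placed at the
#' midpoint). Each individual draws ancestry from every subpopulation
#' proportionally to the Normal(0, sigma) density of their distance,
#' modelling spread by random walk; rows are normalized to sum to one.
#' As sigma shrinks to zero each row degenerates to a one-hot assignment
#' to the nearest subpopulation (ties to the lower index).
#'
#' @param n Number of individuals.
#' @param K Number of intermediate subpopulations.
#' @param sigma Spread of the random walk (> 0).
#' @return n x K matrix of admixture proportions Q.
#' @export
admix_props_1d <- function(n, K, sigma) {
  if (sigma <= 0) stop("`sigma` must be > 0")
  y <- if (n == 1) (K + 1) / 2 else 1 / 2 + (0:(n - 1)) / (n - 1) * K
  Q <- outer(y, 1:K, function(a, b) stats::dnorm(abs(a - b), 0, sigma))
  rs <- rowSums(Q)
  bad <- rs == 0 # density underflow at tiny sigma: degenerate one-hot limit
  if (any(bad)) {
    u <- nearest_subpop(y[bad], K)
    Q[bad, ] <- 0
    Q[cbind(which(bad), u)] <- 1
    rs[bad] <- 1
  }
  Q / rs
}

nearest_subpop <- function(y, K) pmin(pmax(ceiling(y - 0.5), 1L), K)

#' Geographic clustering of admixed individuals
#'
#' Assigns each of the n evenly-spaced individuals of the 1D geography to
#' its nearest intermediate subpopulation (ties broken toward the lower
#' index). On the standard grid this yields K equal-sized clusters; it is
#' the partition handed to F_ST estimators that require subpopulations, and
#' to [a_min_subpops()].
#'
#' @inheritParams admix_props_1d
#' @return Length-n integer vector of cluster indices in 1..K.
#' @export
assign_subpops_1d <- function(n, K) {
  y <- if (n == 1) (K + 1) / 2 else 1 / 2 + (0:(n - 1)) / (n - 1) * K
  nearest_subpop(y, K)
}

# bias coefficient of the admixture model as a function of sigma only
# (tau cancels): s = [ (1/n) sum_u u (sum_j q_ju)^2 ] / [ sum_u u sum_j q_ju^2 ]
bias_coefficient_sigma <- function(sigma, n, K) {
  Q <- admix_props_1d(n, K, sigma)
  u <- 1:K
  (sum(u * colSums(Q)^2) / n) / sum(u * colSums(Q^2))
}

#' Solve for the admixture spread giving a target bias coefficient
#'
#' Under the linear differentiation gradient the bias coefficient
#' \eqn{s^T = \bar\theta / F_{ST}} of the 1D admixture model depends only
#' on sigma, and increases monotonically from 1/K (no spread, independent
#' blocks) to 1 (complete admixture). A bracketed root search finds the
#' sigma matching `s_target` (about 1.78 for s = 1/2, n = 1000, K = 10).
#'
#' @param s_target Target bias coefficient in `(1/K, 1)`.
#' @inheritParams admix_props_1d
#' @param interval Search bracket for sigma.
#' @param tol Root tolerance.
#' @return The solved sigma.
#' @export
solve_sigma <- function(s_target, n, K, interval = c(0.01, 100), tol = 1e-10) {
  if (s_target <= 1 / K || s_target >= 1)
    stop("`s_target` must be in (1/K, 1)")
  g <- function(sig) bias_coefficient_sigma(sig, n, K) - s_target
  lo <- g(interval[1]); hi <- g(interval[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0)
    stop("no sign change in the sigma bracket [", interval[1], ", ",
         interval[2], "]")
  stats::uniroot(g, interval, f.lower = lo, f.upper = hi, tol = tol)$root
}

#' Differentiation scale for the admixture model
#'
#' For fixed admixture proportions Q the generalized F_ST (uniform weights)
#' is linear in tau, giving the closed form
#' \deqn{\tau = F_{ST} \Big/ \frac{1}{K} \sum_u u \cdot
#'   \frac{1}{n} \sum_j q_{ju}^2}
#' (about 0.901 for F_ST = 0.1 at the sigma solved for s = 1/2).
#'
#' @param fst_target Desired generalized F_ST.
#' @param Q n x K admixture proportion matrix.
#' @param K Number of intermediate subpopulations.
#' @return The scale tau.
#' @export
tau_admix <- function(fst_target, Q, K = ncol(Q)) {
  den <- sum((1:K) * colMeans(Q^2)) / K
  if (den <= 0) stop("invalid admixture proportions")
  tau <- fst_target / den
  if (tau > 1) stop("target F_ST infeasible: tau = ", signif(tau, 4), " > 1")
  tau
}

#' True coancestry of an admixture model
#'
#' Under the BN-PSD model the coancestry between individuals is the
#' admixture-weighted mix of the intermediate differentiations,
#' \eqn{\theta_{jk}^T = \sum_u q_{ju} q_{ku} f_{S_u}^T}, i.e.
#' \eqn{\Theta = Q \, diag(f) \, Q^\top} (positive semidefinite). Its
#' diagonal holds the inbreeding coefficients, so the generalized F_ST is
#' the weighted mean diagonal.
#'
#' @param Q n x K admixture proportion matrix.
#' @param f_inter Length-K intermediate differentiations.
#' @return Coancestry-form [relatedness_matrix()].
#' @export
true_coancestry_admix <- function(Q, f_inter) {
  if (ncol(Q) != length(f_inter)) stop("dimension mismatch")
  theta <- Q %*% (f_inter * t(Q))
  relatedness_matrix(theta, form = "coancestry", check_range = TRUE)
}

#' Individual-specific allele frequencies of the admixture model
#'
#' \eqn{\pi_{ij} = \sum_u p_{i S_u} q_{ju}}: each individual's latent
#' frequency is the admixture-weighted average of the intermediate
#' subpopulation frequencies.
#'
#' @param P_sub Loci x K matrix of intermediate subpopulation frequencies.
#' @param Q n x K admixture proportion matrix.
#' @return Loci x n IAF matrix.
#' @export
draw_iafs <- function(P_sub, Q) {
  if (ncol(P_sub) != ncol(Q)) stop("dimension mismatch")
  P <- P_sub %*% t(Q)
  # guard floating-point excursions outside [0, 1]
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

#' Draw genotypes from individual-specific allele frequencies
#'
#' Independent \eqn{Binomial(2, \pi_{ij})} dosages.
#'
#' @param P Loci x n IAF matrix.
#' @return Loci x n integer dosage matrix.
#' @export
draw_genotypes <- function(P) {
  X <- stats::rbinom(length(P), 2L, P)
  dim(X) <- dim(P)
  dimnames(X) <- dimnames(P)
  X
}

#' Simulate the independent-subpopulations model
#'
#' K independent subpopulations with differentiations on the linear
#' gradient [f_intermediate()] scaled to the target F_ST, random sample
#' sizes, Balding-Nichols subpopulation frequencies and binomial genotypes.
#' The true coancestry matrix is block-diagonal (zero between
#' subpopulations) and the returned weights \eqn{w_j = 1/(K r_u)} weigh
#' subpopulations equally, so the generalized F_ST equals the mean
#' intermediate differentiation and the bias coefficient is exactly 1/K.
#'
#' @param n,m,K Numbers of individuals, loci and subpopulations.
#' @param fst Target generalized F_ST.
#' @param sizes Optional fixed sample sizes (length K, summing to n);
#'   drawn by [random_subpop_sizes()] when `NULL`.
#' @param freq_range Ancestral frequency range.
#' @param seed Optional integer seed (recorded in the output).
#' @return List of class `kinfst_sim` with elements `X` (loci x n dosages),
#'   `iafs` (loci x n, here the subpopulation frequency of each individual),
#'   `freqs_subpop` (loci x K), `p_anc`, `labels`, `sizes`, `f_inter`,
#'   `theta` (true coancestry), `weights`, `fst`, `model`, `seed`.
#' @export
simulate_indep <- function(n = 1000, m = 10000, K = 10, fst = 0.1,
                           sizes = NULL, freq_range = c(0.01, 0.5),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < K || K < 2) stop("need n >= K >= 2")
  tau <- tau_indep(fst, K)
  f_inter <- f_intermediate(K, tau)
  if (is.null(sizes)) sizes <- random_subpop_sizes(n, K)
  if (length(sizes) != K || sum(sizes) != n) stop("invalid `sizes`")
  labels <- rep(1:K, sizes)
  p_anc <- draw_ancestral_freqs(m, freq_range)
  P_sub <- vapply(f_inter, function(f) draw_bn_freqs(p_anc, f),
                  numeric(m))
  dim(P_sub) <- c(m, K) # vapply drops the dimension when m = 1
  P <- P_sub[, labels, drop = FALSE]
  X <- draw_genotypes(P)
  Q <- diag(K)[labels, , drop = FALSE] # one-hot admixture
  theta <- true_coancestry_admix(Q, f_inter)
  weights <- 1 / (K * sizes[labels])
  structure(list(X = X, iafs = P, freqs_subpop = P_sub, p_anc = p_anc,
                 labels = labels, sizes = sizes, f_inter = f_inter,
                 theta = theta, weights = weights, fst = fst, K = K,
                 model = "indep", seed = seed),
            class = "kinfst_sim")
}

#' Simulate the 1D-geography admixture model
#'
#' The BN-PSD admixture scenario: intermediate subpopulations on a line
#' with serially increasing differentiation, individuals admixed by
#' Normal random-walk spread ([admix_props_1d()]), latent IAFs
#' \eqn{\pi = P_{sub} Q^\top} and binomial genotypes. The spread sigma is
#' solved so the bias coefficient matches `s_target` (default 1/2, which
#' halves the standard plug-in F_ST estimate) and tau so the generalized
#' F_ST (uniform weights) matches `fst`. The true coancestry matrix is
#' smooth with no zero blocks. `labels` holds the geographic clustering
#' used by subpopulation-based estimators.
#'
#' @inheritParams simulate_indep
#' @param s_target Target bias coefficient in `(1/K, 1)`.
#' @param sigma Optional spread override (skips the root solve).
#' @return List of class `kinfst_sim`; in addition to the fields of
#'   [simulate_indep()] it carries `Q`, `sigma` and `tau`.
#' @export
simulate_admix <- function(n = 1000, m = 10000, K = 10, fst = 0.1,
                           s_target = 0.5, sigma = NULL,
                           freq_range = c(0.01, 0.5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < K || K < 2) stop("need n >= K >= 2")
  if (is.null(sigma)) sigma <- solve_sigma(s_target, n, K)
  Q <- admix_props_1d(n, K, sigma)
  tau <- tau_admix(fst, Q)
  f_inter <- f_intermediate(K, tau)
  p_anc <- draw_ancestral_freqs(m, freq_range)
  P_sub <- vapply(f_inter, function(f) draw_bn_freqs(p_anc, f),
                  numeric(m))
  dim(P_sub) <- c(m, K)
  P <- draw_iafs(P_sub, Q)
  X <- draw_genotypes(P)
  theta <- true_coancestry_admix(Q, f_inter)
  labels <- assign_subpops_1d(n, K)
  structure(list(X = X, iafs = P, freqs_subpop = P_sub, p_anc = p_anc,
                 labels = labels, sizes = as.vector(table(labels)),
                 f_inter = f_inter, theta = theta,
                 weights = uniform_weights(n), fst = fst, K = K,
                 Q = Q, sigma = sigma, tau = tau,
                 model = "admix", seed = seed),
            class = "kinfst_sim")
}
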
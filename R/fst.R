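# All multi-locus F_ST estimators here follow the ratio-of-means discipline:
# per-locus numerator and denominator terms are summed across loci first and
# divided once, never averaged as per-locus ratios.

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("F_ST estimate (%s): %.6g\n", x$method, x$value))
  cat(sprintf("  numerator sum:   %.6g\n  denominator sum: %.6g\n",
              x$numerator_sum, x$denominator_sum))
  invisible(x)
}

fst_estimate <- function(value, method, numerator_sum, denominator_sum) {
  structure(list(value = value, method = method,
                 numerator_sum = numerator_sum,
                 denominator_sum = denominator_sum),
            class = "fst_estimate")
}

# per-group sample allele frequencies, heterozygote fractions and sizes
group_stats <- function(X, labels) {
  check_genotypes(X)
  if (length(labels) != ncol(X))
    stop("`labels` must have one entry per individual (column of `X`)")
  labels <- as.factor(labels)
  if (nlevels(labels) < 2)
    stop("need at least 2 subpopulations")
  Z <- stats::model.matrix(~ labels - 1)
  sizes <- as.vector(colSums(Z))
  p_hat <- sweep(X %*% Z, 2, 2 * sizes, "/")
  h_hat <- sweep((X == 1) %*% Z, 2, sizes, "/")
  list(p_hat = p_hat, h_hat = h_hat, sizes = sizes,
       groups = levels(labels))
}

#' F_ST estimator for independent subpopulations
#'
#' The simplified estimator that Weir-Cockerham, Weir-Hill and HudsonK all
#' reduce to when subpopulation sample sizes go to infinity (so sample
#' frequencies equal true subpopulation frequencies and small-sample
#' corrections vanish):
#' \deqn{\hat F_{ST}^{indep} = \frac{\sum_i \hat\sigma_i^2}
#'   {\sum_i \hat p_i (1 - \hat p_i) + \hat\sigma_i^2 / n},}
#' with \eqn{\hat p_i} the unweighted row mean and \eqn{\hat\sigma_i^2} the
#' unbiased (n-1 denominator) variance across the n columns. It is
#' consistent under independent subpopulations, but under arbitrary
#' coancestry converges to \eqn{(F_{ST} - \tilde\theta)/(1 - \tilde\theta)}
#' where \eqn{\tilde\theta} is the mean between-column coancestry (see
#' [limit_fst_indep()]).
#'
#' @param P Loci x columns matrix of true subpopulation (or
#'   individual-specific) allele frequencies in `[0, 1]`.
#' @return An `fst_estimate` (list with `value`, `method`,
#'   `numerator_sum`, `denominator_sum`).
#' @export
fst_indep <- function(P) {
  check_iafs(P)
  n <- ncol(P)
  if (n < 2) stop("need at least 2 columns")
  p <- rowMeans(P)
  s2 <- rowSums((P - p)^2) / (n - 1)
  num <- sum(s2)
  den <- sum(p * (1 - p) + s2 / n)
  fst_estimate(num / den, "indep", num, den)
}

#' Weir-Cockerham F_ST estimator
#'
#' The classical ratio-of-means estimator for K independent subpopulations
#' sharing one differentiation parameter, with its size-imbalance (C^2) and
#' heterozygosity small-sample corrections, exactly as printed in its
#' source. `fst_wc()` computes per-group sample frequencies and heterozygote
#' fractions from genotypes; `fst_wc_core()` takes them directly (useful for
#' studying the estimator's limit: with `sizes = Inf` the small-sample
#' corrections are dropped and the computation coincides with
#' [fst_indep()]).
#'
#' @param X Loci x individuals dosage matrix.
#' @param labels Length-n subpopulation assignment (>= 2 groups, all
#'   nonempty).
#' @return An `fst_estimate`.
#' @export
fst_wc <- function(X, labels) {
  g <- group_stats(X, labels)
  fst_wc_core(g$p_hat, g$sizes, g$h_hat)
}

#' @rdname fst_wc
#' @param p_hat Loci x K matrix of per-group sample allele frequencies.
#' @param sizes Length-K group sample sizes, or `Inf` for the
#'   infinite-sample-size reduction (equal weights).
#' @param h_hat Loci x K matrix of per-group heterozygote fractions
#'   (unused, and may be omitted, when `sizes = Inf`).
#' @export
fst_wc_core <- function(p_hat, sizes, h_hat = NULL) {
  r <- ncol(p_hat)
  if (r < 2) stop("need at least 2 subpopulations")
  if (all(is.infinite(sizes))) {
    pT <- rowMeans(p_hat)
    s2 <- rowSums((p_hat - pT)^2) / (r - 1)
    num <- sum(s2)
    den <- sum(pT * (1 - pT) + s2 / r)
    return(fst_estimate(num / den, "wc", num, den))
  }
  if (length(sizes) != r || any(sizes < 1)) stop("invalid group sizes")
  if (is.null(h_hat)) stop("`h_hat` is required for finite sample sizes")
  nbar <- mean(sizes)
  C2 <- sum((sizes - nbar)^2) / (nbar^2 * (r - 1))
  wsz <- sizes / nbar
  pT <- as.vector(p_hat %*% wsz) / r
  hbar <- as.vector(h_hat %*% wsz) / r
  s2 <- as.vector(((p_hat - pT)^2) %*% wsz) / (r - 1)
  pq <- pT * (1 - pT)
  cc <- nbar * C2 / (r * (nbar - 1))
  num <- s2 - (pq - (r - 1) / r * s2 - hbar / 4) / (nbar - 1)
  den <- pq * (1 - cc) + (s2 / r) * (1 + (r - 1) * cc) + hbar * C2 / (4 * r * (nbar - 1))
  fst_estimate(sum(num) / sum(den), "wc", sum(num), sum(den))
}

#' Weir-Hill F_ST estimator
#'
#' The biallelic Weir-Hill estimator, which allows per-subpopulation
#' differentiation and weighs individuals (not subpopulations) equally via
#' size-proportional weights \eqn{w_j = n_j / \sum n_j}:
#' \deqn{\hat F_{ST}^{WH} = 1 - \frac{\left(\sum_j n_j (1 - w_j)\right)
#'   \sum_i \sum_j w_j \frac{2 n_j}{2 n_j - 1} \hat p_{ij}(1 - \hat p_{ij})}
#'   {\sum_i \sum_j n_j (\hat p_{ij} - \hat p_i^T)^2 +
#'    n_j (1 - w_j) \hat p_{ij}(1 - \hat p_{ij})}.}
#' Under arbitrary coancestry it targets the linearly-transformed
#' \eqn{(F_{ST} - \tilde\theta)/(1 - \tilde\theta)}. With `sizes = Inf`
#' (equal weights) the computation reduces to [fst_indep()].
#'
#' @inheritParams fst_wc
#' @return An `fst_estimate`.
#' @export
fst_weir_hill <- function(X, labels) {
  g <- group_stats(X, labels)
  fst_weir_hill_core(g$p_hat, g$sizes)
}

#' @rdname fst_weir_hill
#' @inheritParams fst_wc_core
#' @export
fst_weir_hill_core <- function(p_hat, sizes) {
  r <- ncol(p_hat)
  if (r < 2) stop("need at least 2 subpopulations")
  if (all(is.infinite(sizes))) {
    pT <- rowMeans(p_hat)
    s2 <- rowSums((p_hat - pT)^2) / (r - 1)
    num <- sum(s2)
    den <- sum(pT * (1 - pT) + s2 / r)
    return(fst_estimate(num / den, "weir_hill", num, den))
  }
  if (length(sizes) != r || any(sizes < 1)) stop("invalid group sizes")
  w <- sizes / sum(sizes)
  pT <- as.vector(p_hat %*% w)
  pq <- p_hat * (1 - p_hat)
  Z <- sum(sweep((p_hat - pT)^2, 2, sizes, "*") +
             sweep(pq, 2, sizes * (1 - w), "*"))
  Y <- sum(sweep(pq, 2, w * 2 * sizes / (2 * sizes - 1), "*"))
  Xc <- sum(sizes * (1 - w))
  fst_estimate(1 - Xc * Y / Z, "weir_hill", Z - Xc * Y, Z)
}

#' Hudson pairwise F_ST estimator
#'
#' Measures the differentiation of exactly two subpopulations:
#' \deqn{\hat F_{ST}^{Hudson} = \frac{\sum_i (\hat p_{i1} - \hat p_{i2})^2
#'   - \frac{\hat p_{i1}(1-\hat p_{i1})}{2 n_1 - 1}
#'   - \frac{\hat p_{i2}(1-\hat p_{i2})}{2 n_2 - 1}}
#'   {\sum_i \hat p_{i1}(1 - \hat p_{i2}) + \hat p_{i2}(1 - \hat p_{i1})}.}
#' For independent subpopulations it converges to the mean of their two
#' differentiation parameters. Symmetric in the two groups.
#'
#' @inheritParams fst_wc
#' @return An `fst_estimate`.
#' @export
fst_hudson_pair <- function(X, labels) {
  g <- group_stats(X, labels)
  if (length(g$sizes) != 2)
    stop("the Hudson pairwise estimator requires exactly 2 subpopulations")
  fst_hudson_pair_core(g$p_hat, g$sizes)
}

#' @rdname fst_hudson_pair
#' @inheritParams fst_wc_core
#' @export
fst_hudson_pair_core <- function(p_hat, sizes) {
  if (ncol(p_hat) != 2 || length(sizes) != 2)
    stop("exactly 2 subpopulations are required")
  p1 <- p_hat[, 1]; p2 <- p_hat[, 2]
  corr <- if (all(is.infinite(sizes))) 0 else {
    if (any(2 * sizes - 1 <= 0)) stop("group sizes must satisfy 2n - 1 > 0")
    p1 * (1 - p1) / (2 * sizes[1] - 1) + p2 * (1 - p2) / (2 * sizes[2] - 1)
  }
  num <- sum((p1 - p2)^2 - corr)
  den <- sum(p1 * (1 - p2) + p2 * (1 - p1))
  fst_estimate(num / den, "hudson", num, den)
}

#' HudsonK F_ST estimator for K subpopulations
#'
#' Generalizes the Hudson pairwise estimator to K subpopulations by
#' averaging the numerators and denominators of all pairwise estimators
#' before taking the single ratio, which simplifies to
#' \deqn{\hat F_{ST}^{HudsonK} = \frac{\sum_i \hat\sigma_i^2 - \frac{1}{K}
#'   \sum_j \frac{\hat p_{ij}(1-\hat p_{ij})}{2 n_j - 1}}
#'   {\sum_i \hat p_i^T (1 - \hat p_i^T) + \hat\sigma_i^2 / K},}
#' with equal subpopulation weights (\eqn{\hat p_i^T} is the unweighted
#' group mean). Equals the Weir-Goudet subpopulation estimator for biallelic
#' loci, and for K = 2 equals the pairwise estimator exactly. Consistent
#' under independent subpopulations; `sizes = Inf` reduces to
#' [fst_indep()].
#'
#' @inheritParams fst_wc
#' @return An `fst_estimate`.
#' @export
fst_hudson_k <- function(X, labels) {
  g <- group_stats(X, labels)
  fst_hudson_k_core(g$p_hat, g$sizes)
}

#' @rdname fst_hudson_k
#' @inheritParams fst_wc_core
#' @export
fst_hudson_k_core <- function(p_hat, sizes) {
  r <- ncol(p_hat)
  if (r < 2) stop("need at least 2 subpopulations")
  pT <- rowMeans(p_hat)
  s2 <- rowSums((p_hat - pT)^2) / (r - 1)
  corr <- if (all(is.infinite(sizes))) 0 else {
    if (length(sizes) != r || any(2 * sizes - 1 <= 0))
      stop("group sizes must satisfy 2n - 1 > 0")
    as.vector((p_hat * (1 - p_hat)) %*% (1 / (2 * sizes - 1))) / r
  }
  num <- sum(s2 - corr)
  den <- sum(pT * (1 - pT) + s2 / r)
  fst_estimate(num / den, "hudson_k", num, den)
}

#' Plug-in F_ST from the standard kinship/coancestry estimator
#'
#' The weighted mean of standard inbreeding estimates. Remarkably, all
#' three genotype inbreeding variants of [inbreeding_std()] give *exactly*
#' the same plug-in value when the F_ST weights match those of the allele
#' frequency estimate, which simplifies to
#' \deqn{\hat F_{ST}^{std} = \frac{\sum_i \sum_j w_j (x_{ij} - 2\hat p_i)^2}
#'   {2 \sum_i \hat p_i (1 - \hat p_i)} - 1} for genotypes
#' (`fst_std()`), and for IAFs (`fst_std_iaf()`)
#' \deqn{\hat F_{ST}^{std} = \frac{\sum_i \sum_j w_j (\pi_{ij} - \hat p_i)^2}
#'   {\sum_i \hat p_i (1 - \hat p_i)}.}
#' Both are downwardly biased under structure, converging to
#' \eqn{(F_{ST} - \bar\phi)/(1 - \bar\phi)} (resp. \eqn{\bar\theta}); see
#' [limit_fst_std()] and the oracle adjustments [fst_adjust_theta()] /
#' [fst_adjust_s()].
#'
#' @inheritParams kinship_std
#' @return An `fst_estimate` (its `numerator_sum` and `denominator_sum`
#'   satisfy `value = numerator_sum / denominator_sum`).
#' @export
fst_std <- function(X, weights = NULL) {
  check_genotypes(X)
  w <- validate_weights(weights, ncol(X), positive = TRUE)
  p <- as.vector(X %*% w) / 2
  den <- 2 * sum(p * (1 - p))
  if (den == 0)
    stop("all loci are monomorphic under the estimated allele frequencies")
  num <- sum(((X - 2 * p)^2) %*% w)
  fst_estimate(num / den - 1, "std", num - den, den)
}

#' @rdname fst_std
#' @param P Loci x individuals IAF matrix.
#' @export
fst_std_iaf <- function(P, weights = NULL) {
  check_iafs(P)
  w <- validate_weights(weights, ncol(P), positive = TRUE)
  p <- as.vector(P %*% w)
  den <- sum(p * (1 - p))
  if (den == 0) stop("all loci are fixed under the estimated allele frequencies")
  num <- sum(((P - p)^2) %*% w)
  fst_estimate(num / den, "std_iaf", num, den)
}

as_fst_value <- function(x) if (inherits(x, "fst_estimate")) x$value else x

#' Oracle bias adjustments of the standard plug-in F_ST
#'
#' Two consistent "oracle" corrections of [fst_std()] that require
#' information unavailable in practice. `fst_adjust_theta()` inverts the
#' bias given the true weighted mean coancestry \eqn{\bar\theta}:
#' \eqn{\hat F_{ST}' = \hat F_{ST}^{std}(1 - \bar\theta) + \bar\theta}.
#' `fst_adjust_s()` uses the bias coefficient \eqn{s = \bar\theta / F_{ST}}
#' instead: \eqn{\hat F_{ST}'' = \hat F_{ST}^{std} /
#' (1 - s(1 - \hat F_{ST}^{std}))}. With uniform weights and s = 1/n,
#' `fst_adjust_s()` applied to `fst_std_iaf()` reproduces [fst_indep()]
#' exactly, so it generalizes the independent-subpopulations estimator.
#'
#' @param fst_std An `fst_estimate` from [fst_std()] / [fst_std_iaf()], or
#'   its numeric value.
#' @param theta_bar True weighted mean coancestry, in `[0, 1)`.
#' @return Adjusted F_ST value (numeric scalar).
#' @export
fst_adjust_theta <- function(fst_std, theta_bar) {
  f <- as_fst_value(fst_std)
  if (theta_bar < 0 || theta_bar >= 1) stop("`theta_bar` must be in [0, 1)")
  f * (1 - theta_bar) + theta_bar
}

#' @rdname fst_adjust_theta
#' @param s Bias coefficient in `(0, 1]` (see [bias_coefficient()]).
#' @export
fst_adjust_s <- function(fst_std, s) {
  f <- as_fst_value(fst_std)
  if (s <= 0 || s > 1) stop("`s` must be in (0, 1]")
  den <- 1 - s * (1 - f)
  if (abs(den) < 1e-12) stop("adjustment denominator 1 - s(1 - fst) is ~0")
  f / den
}

#' New F_ST estimator
#'
#' The weighted mean of the new inbreeding estimates,
#' \eqn{\hat F_{ST}^{new} = \sum_j w_j (2 \hat\phi_{jj}^{new} - 1)}.
#' Consistent for locally-outbred individuals whenever the kinship matrix
#' comes from [kinship_new()] with a consistent minimum estimate.
#'
#' @param K_new Kinship-form [relatedness_matrix()] from [kinship_new()].
#' @param weights Weight vector or `NULL` for uniform.
#' @return An `fst_estimate`.
#' @export
fst_new <- function(K_new, weights = NULL) {
  f <- inbreeding_new(K_new)
  w <- validate_weights(weights, length(f))
  v <- sum(w * f)
  fst_estimate(v, "new", v, 1)
}

#' Weir-Goudet individual-level F_ST estimator
#'
#' The unweighted mean of the Weir-Goudet inbreeding estimates,
#' \eqn{\frac{1}{n} \sum_j (2 \hat\phi_{jj}^{WG} - 1)}. Targets the
#' linearly-transformed value \eqn{(F_{ST} - \tilde\phi)/(1 - \tilde\phi)},
#' not the IBD probability.
#'
#' @param K_wg Kinship-form [relatedness_matrix()] from [kinship_wg()].
#' @return An `fst_estimate`.
#' @export
fst_wg_individuals <- function(K_wg) {
  if (rel_form(K_wg) != "kinship") stop("`K_wg` must be in kinship form")
  v <- mean(2 * diag(K_wg) - 1)
  fst_estimate(v, "wg", v, 1)
}
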
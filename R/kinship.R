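# Genotype matrices are loci x individuals (m x n): x_ij is the dosage of
# the reference allele at locus i for individual j, in {0, 1, 2}.

check_genotypes <- function(X) {
  if (!is.matrix(X)) stop("`X` must be a matrix (loci x individuals)")
  if (anyNA(X))
    stop("genotype matrix has missing entries; estimators require complete ",
         "dosages (see read_genotypes() for explicit missing-data handling)")
  rng <- range(X)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must be in {0, 1, 2}")
  invisible(X)
}

check_iafs <- function(P) {
  if (!is.matrix(P)) stop("`P` must be a matrix (loci x individuals)")
  if (anyNA(P)) stop("IAF matrix has missing entries")
  if (min(P) < 0 || max(P) > 1) stop("allele frequencies must be in [0, 1]")
  invisible(P)
}

# row-blocked index sets over m loci, to cap transient double copies
row_blocks <- function(m, block_size) {
  if (m < 1L) stop("need at least one locus")
  starts <- seq.int(1L, m, by = block_size)
  lapply(starts, function(s) s:min(s + block_size - 1L, m))
}

#' Estimate ancestral allele frequencies
#'
#' Weighted per-locus allele frequency estimates relative to the ancestral
#' population: \eqn{\hat p_i = \frac{1}{2}\sum_j w_j x_{ij}} for genotype
#' dosages, or \eqn{\hat p_i = \sum_j w_j \pi_{ij}} for individual-specific
#' allele frequencies (IAFs). Weights must be strictly positive and sum to
#' one so that the estimate is unbiased and stays in `[0, 1]`. Note that
#' under population structure this estimator is unbiased but *not*
#' consistent: its variance is proportional to the weighted mean kinship
#' and need not vanish as n grows, which is the root cause of the bias of
#' the standard kinship estimator.
#'
#' @param X Loci x individuals matrix: dosages in `{0,1,2}` when
#'   `input = "genotypes"`, frequencies in `[0,1]` when `input = "iafs"`.
#' @param weights Length-n weight vector or `NULL` for uniform.
#' @param input Interpretation of `X`.
#' @return Length-m vector of estimated allele frequencies.
#' @export
estimate_freqs <- function(X, weights = NULL, input = c("genotypes", "iafs")) {
  input <- match.arg(input)
  if (input == "genotypes") check_genotypes(X) else check_iafs(X)
  w <- validate_weights(weights, ncol(X), positive = TRUE)
  p <- as.vector(X %*% w)
  if (input == "genotypes") p <- p / 2
  p
}

#' Standard kinship estimator
#'
#' The most commonly-used method-of-moments kinship estimator (the basis of
#' the usual genetic relatedness matrix), generalized to weighted allele
#' frequency estimates and written as a ratio-of-means estimator:
#' \deqn{\hat\phi_{jk} = \frac{\sum_i (x_{ij} - 2\hat p_i)(x_{ik} - 2\hat p_i)}
#'   {4 \sum_i \hat p_i (1 - \hat p_i)}.}
#' It centers genotypes by locus and normalizes by an estimate of
#' \eqn{4 p_i(1-p_i)}. Under population structure it converges not to the
#' kinship matrix but to a doubly-centered transformation of it (see
#' [limit_kinship_std()]), so entries can be negative.
#'
#' The `"mean_of_ratios"` form, prevalent in the literature, averages the
#' per-locus ratios \eqn{(x_{ij}-2\hat p_i)(x_{ik}-2\hat p_i) /
#' (4 \hat p_i(1-\hat p_i))} over the loci with \eqn{\hat p_i \notin \{0,1\}}
#' (fixed loci are skipped and their count attached as attribute
#' `n_skipped`). It is noisier than the ratio-of-means form and its
#' convergence value is not characterized.
#'
#' @param X Loci x individuals dosage matrix.
#' @param weights Weights for the allele-frequency estimate (`NULL` =
#'   uniform); must be strictly positive.
#' @param form `"ratio_of_means"` (recommended) or `"mean_of_ratios"`.
#' @param block_size Number of loci per accumulation block.
#' @return n x n kinship-form [relatedness_matrix()].
#' @export
kinship_std <- function(X, weights = NULL,
                        form = c("ratio_of_means", "mean_of_ratios"),
                        block_size = 10000L) {
  form <- match.arg(form)
  check_genotypes(X)
  n <- ncol(X)
  if (n < 2) stop("need at least 2 individuals")
  w <- validate_weights(weights, n, positive = TRUE)
  p <- as.vector(X %*% w) / 2
  C <- matrix(0, n, n)
  if (form == "ratio_of_means") {
    den <- 4 * sum(p * (1 - p))
    if (den == 0)
      stop("all loci are monomorphic under the estimated allele frequencies")
    for (idx in row_blocks(nrow(X), block_size)) {
      Xc <- X[idx, , drop = FALSE] - 2 * p[idx]
      C <- C + crossprod(Xc)
    }
    out <- C / den
  } else {
    keep <- p > 0 & p < 1
    if (!any(keep))
      stop("all loci are monomorphic under the estimated allele frequencies")
    n_skipped <- sum(!keep)
    if (n_skipped > 0)
      message("kinship_std(mean_of_ratios): skipped ", n_skipped,
              " fixed loci (estimated allele frequency 0 or 1)")
    for (idx in row_blocks(nrow(X), block_size)) {
      sub <- idx[keep[idx]]
      if (!length(sub)) next
      Xs <- (X[sub, , drop = FALSE] - 2 * p[sub]) / (2 * sqrt(p[sub] * (1 - p[sub])))
      C <- C + crossprod(Xs)
    }
    out <- C / sum(keep)
    attr(out, "n_skipped") <- n_skipped
  }
  dimnames(out) <- list(colnames(X), colnames(X))
  relatedness_matrix(out, form = "kinship")
}

#' Standard inbreeding estimators
#'
#' Ratio-of-means inbreeding estimators built on the weighted allele
#' frequency estimates \eqn{\hat p_i}:
#' * `"std"`: \eqn{2\hat\phi_{jj} - 1} from the diagonal of [kinship_std()];
#' * `"stdII"`: \eqn{1 - \sum_i x_{ij}(2 - x_{ij}) / (2\sum_i \hat p_i(1-\hat p_i))},
#'   a heterozygosity-deficit estimator (equal to 1 for a fully homozygous
#'   individual at polymorphic loci);
#' * `"stdIII"`: \eqn{\sum_i (x_{ij}^2 - (1 + 2\hat p_i)x_{ij} + 2\hat p_i^2)
#'   / (2\sum_i \hat p_i(1-\hat p_i))}.
#'
#' All three converge to different linear transformations of the true
#' inbreeding under structure, yet plugging any of them into the weighted
#' generalized F_ST definition gives *exactly* the same estimate when the
#' F_ST weights match those used for \eqn{\hat p_i} (see [fst_std()]).
#'
#' @inheritParams kinship_std
#' @param variant Which estimator to compute.
#' @return Length-n vector of inbreeding estimates.
#' @export
inbreeding_std <- function(X, weights = NULL,
                           variant = c("std", "stdII", "stdIII")) {
  variant <- match.arg(variant)
  check_genotypes(X)
  n <- ncol(X)
  w <- validate_weights(weights, n, positive = TRUE)
  p <- as.vector(X %*% w) / 2
  den <- 2 * sum(p * (1 - p))
  if (den == 0)
    stop("all loci are monomorphic under the estimated allele frequencies")
  switch(variant,
    # 2 * phi_jj - 1 with phi_jj = colSums((X - 2p)^2) / (4 sum p(1-p))
    std = colSums((X - 2 * p)^2) / den - 1,
    stdII = 1 - colSums(X * (2 - X)) / den,
    stdIII = colSums(X^2 - (1 + 2 * p) * X + 2 * p^2) / den
  )
}

#' Pairwise A statistic
#'
#' The building block of the new kinship estimator:
#' \deqn{A_{jk} = \frac{1}{m} \sum_i (x_{ij} - 1)(x_{ik} - 1) - 1,}
#' computed for all pairs including j = k. Its expectation is
#' \eqn{(\phi_{jk}^T - 1) v_m^T} with the shared positive nuisance scale
#' \eqn{v_m^T = \frac{4}{m}\sum_i p_i^T (1 - p_i^T)}: unlike the standard
#' estimator, its bias is uniform across pairs, so a single consistent
#' estimate of the scale (from a least-related pair, [a_min_subpops()])
#' unbiases the whole matrix. Dosage bounds confine every entry to
#' `[-2, 0]`.
#'
#' @inheritParams kinship_std
#' @return n x n symmetric matrix with attribute `m_loci`.
#' @export
a_statistic <- function(X, block_size = 10000L) {
  check_genotypes(X)
  m <- nrow(X)
  if (m == 0) stop("need at least one locus")
  n <- ncol(X)
  C <- matrix(0, n, n)
  for (idx in row_blocks(m, block_size))
    C <- C + crossprod(X[idx, , drop = FALSE] - 1)
  A <- C / m - 1
  dimnames(A) <- list(colnames(X), colnames(X))
  attr(A, "m_loci") <- m
  A
}

#' Minimum between-subpopulation mean of the A statistic
#'
#' Proof-of-principle estimator of the (negative) nuisance scale of the
#' A statistic: the minimum, over all unordered pairs of distinct
#' subpopulations, of the unweighted mean \eqn{A_{jk}} between them,
#' \deqn{\hat A_{\min} = \min_{u \ne v} \frac{1}{|S_u| |S_v|}
#'   \sum_{j \in S_u} \sum_{k \in S_v} A_{jk}.}
#' It consistently estimates \eqn{-v^T} provided the least related pair of
#' subpopulations has zero kinship, which sets the reference T to the MRCA
#' population. The subpopulations need not be independent or unstructured;
#' only the existence of one unrelated pair of groups matters. Ties in the
#' minimum are value-identical so no tie-break is needed.
#'
#' @param A Matrix from [a_statistic()].
#' @param labels Length-n vector assigning each individual to a
#'   subpopulation (at least two distinct values).
#' @return The minimum between-subpopulation mean (scalar, negative in any
#'   sane dataset).
#' @export
a_min_subpops <- function(A, labels) {
  n <- nrow(A)
  if (length(labels) != n) stop("`labels` must have length ", n)
  labels <- as.factor(labels)
  K <- nlevels(labels)
  if (K < 2)
    stop("at least 2 subpopulations are required to identify an unrelated ",
         "pair; provide labels with >= 2 groups")
  Z <- stats::model.matrix(~ labels - 1)
  Z <- sweep(Z, 2, colSums(Z), "/") # columns average over each group
  B <- crossprod(Z, A %*% Z)        # K x K matrix of between-group means
  min(B[upper.tri(B)])
}

#' New (consistent) kinship estimator
#'
#' Rescales the A statistic by a consistent estimate of its minimum:
#' \deqn{\hat\phi_{jk}^{new} = 1 - A_{jk} / \hat A_{\min},}
#' applied to all pairs including the diagonal. When \eqn{\hat A_{\min}}
#' converges to the negative nuisance scale \eqn{-v^T} (e.g. via
#' [a_min_subpops()] with a valid partition), this estimator is consistent
#' for the kinship IBD probabilities relative to the MRCA population.
#'
#' @param A Matrix from [a_statistic()].
#' @param a_min Estimate of the minimum mean A value (must be negative).
#' @return n x n kinship-form [relatedness_matrix()].
#' @export
kinship_new <- function(A, a_min) {
  if (!is.numeric(a_min) || length(a_min) != 1 || !is.finite(a_min))
    stop("`a_min` must be a finite scalar")
  if (a_min >= 0)
    stop("`a_min` must be negative; a non-negative value signals that no ",
         "unrelated pair of subpopulations was identified")
  out <- 1 - unclass(A) / a_min
  attr(out, "m_loci") <- NULL
  relatedness_matrix(out, form = "kinship")
}

#' Inbreeding from the new kinship estimator
#'
#' @param K_new Kinship-form [relatedness_matrix()] from [kinship_new()].
#' @return Length-n vector \eqn{2 \hat\phi_{jj} - 1}.
#' @export
inbreeding_new <- function(K_new) {
  if (rel_form(K_new) != "kinship") stop("`K_new` must be in kinship form")
  2 * diag(K_new) - 1
}

#' Weir-Goudet individual-level kinship estimator
#'
#' Identical in structure to [kinship_new()] but rescaling by the *average*
#' off-diagonal A statistic instead of the minimum:
#' \eqn{\hat\phi_{jk}^{WG} = 1 - A_{jk} / \hat A_{avg}} with
#' \eqn{\hat A_{avg}} the unweighted mean over unordered pairs j > k. It
#' targets the linearly-transformed kinship
#' \eqn{(\phi_{jk} - \tilde\phi)/(1 - \tilde\phi)} (see
#' [limit_kinship_wg()]) and recovers the IBD probabilities only when the
#' mean off-diagonal kinship \eqn{\tilde\phi} is zero.
#'
#' @param A Matrix from [a_statistic()].
#' @return n x n kinship-form [relatedness_matrix()].
#' @export
kinship_wg <- function(A) {
  n <- nrow(A)
  if (n < 2) stop("need at least 2 individuals")
  a_avg <- mean(A[upper.tri(A)])
  if (a_avg == 0) stop("mean off-diagonal A statistic is zero")
  out <- 1 - unclass(A) / a_avg
  attr(out, "m_loci") <- NULL
  relatedness_matrix(out, form = "kinship")
}

#' Standard coancestry estimator from individual-specific allele frequencies
#'
#' The IAF analogue of [kinship_std()] (ratio-of-means form):
#' \deqn{\hat\theta_{jk} = \frac{\sum_i (\pi_{ij} - \hat p_i)(\pi_{ik} - \hat p_i)}
#'   {\sum_i \hat p_i (1 - \hat p_i)},}
#' with \eqn{\hat p_i = \sum_j w_j \pi_{ij}}. Access to the latent IAFs
#' removes genotype sampling noise but not the structural bias: the limit is
#' the same doubly-centered transformation as for genotypes (see
#' [limit_coancestry_std()]).
#'
#' @param P Loci x individuals IAF matrix, entries in `[0, 1]`.
#' @inheritParams kinship_std
#' @return n x n coancestry-form [relatedness_matrix()].
#' @export
coancestry_std_iaf <- function(P, weights = NULL, block_size = 10000L) {
  check_iafs(P)
  n <- ncol(P)
  if (n < 2) stop("need at least 2 individuals")
  w <- validate_weights(weights, n, positive = TRUE)
  p <- as.vector(P %*% w)
  den <- sum(p * (1 - p))
  if (den == 0) stop("all loci are fixed under the estimated allele frequencies")
  C <- matrix(0, n, n)
  for (idx in row_blocks(nrow(P), block_size))
    C <- C + crossprod(P[idx, , drop = FALSE] - p[idx])
  out <- C / den
  dimnames(out) <- list(colnames(P), colnames(P))
  relatedness_matrix(out, form = "coancestry")
}
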
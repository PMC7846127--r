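#' Structural inbreeding from Wright's partition
#'
#' Wright partitions the total inbreeding coefficient of an individual,
#' \eqn{f^T} (relative to an ancestral population T), into a local (family)
#' component \eqn{f^L} and a structural (population) component via
#' \eqn{(1 - f^T) = (1 - f^L)(1 - f^{L,T})}. Solving for the structural
#' component gives \eqn{f^{L,T} = (f^T - f^L) / (1 - f^L)}, which is the
#' per-individual F_ST. The result may be negative when the total estimate
#' is smaller than the local pedigree value; it is returned unclamped so
#' callers can see such inconsistencies.
#'
#' @param f_total Total inbreeding coefficient(s) in `[0, 1]`.
#' @param f_local Local (pedigree) inbreeding coefficient(s) in `[0, 1)`.
#'   For n-th cousin parents the pedigree expectation is `1 / 4^(n + 1)`.
#' @return Structural inbreeding coefficient(s), same length as the inputs.
#' @examples
#' wright_partition(0.15, 1 / 16) # first-cousin parents, ~0.093
#' wright_partition(0.15, 1 / 64) # second-cousin parents, ~0.137
#' @export
wright_partition <- function(f_total, f_local) {
  stopifnot(is.numeric(f_total), is.numeric(f_local))
  if (any(f_total < 0 | f_total > 1))
    stop("`f_total` must be in [0, 1]")
  if (any(f_local < 0 | f_local >= 1))
    stop("`f_local` must be in [0, 1)")
  (f_total - f_local) / (1 - f_local)
}

#' Uniform weight vector
#'
#' @param n Number of individuals.
#' @return Numeric vector of length `n`, each entry `1/n`.
#' @export
uniform_weights <- function(n) rep(1 / n, n)

# validate a weight vector: non-negative (strictly positive if required),
# summing to one; NULL means uniform
validate_weights <- function(weights, n, positive = FALSE) {
  if (is.null(weights))
    return(uniform_weights(n))
  if (length(weights) != n)
    stop("`weights` must have length ", n)
  if (positive && any(weights <= 0))
    stop("`weights` must be strictly positive")
  if (any(weights < 0))
    stop("`weights` must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("`weights` must sum to 1")
  weights
}

#' Generalized F_ST as a weighted mean of structural inbreeding
#'
#' The generalized F_ST of n individuals is the weighted average of their
#' per-individual structural inbreeding coefficients,
#' \eqn{F_{ST} = \sum_j w_j f_{L_j}^T}, with non-negative weights summing
#' to one. Weights allow balancing skewed samples; with K equally-weighted
#' subpopulations this reduces to the mean subpopulation-specific F_ST.
#'
#' @param f_structural Length-n vector of structural inbreeding coefficients.
#' @param weights Length-n weight vector, or `NULL` for uniform weights.
#' @return The generalized F_ST (scalar).
#' @export
generalized_fst <- function(f_structural, weights = NULL) {
  weights <- validate_weights(weights, length(f_structural))
  sum(weights * f_structural)
}

#' Construct a relatedness matrix
#'
#' A relatedness matrix is an n x n symmetric matrix of IBD probabilities
#' relative to an ancestral population, in one of two forms that differ only
#' on the diagonal: in `"coancestry"` form the diagonal holds the inbreeding
#' coefficients \eqn{f_j^T}, in `"kinship"` form it holds the self-kinship
#' \eqn{\phi_{jj}^T = (1 + f_j^T)/2}. Off-diagonal entries (the kinship
#' coefficients \eqn{\phi_{jk}^T}) are identical in both forms.
#'
#' True-parameter matrices have entries in `[0, 1]`; *estimated* matrices may
#' contain negative (or > 1) entries, so range is only checked when
#' `check_range = TRUE`.
#'
#' @param values n x n symmetric numeric matrix.
#' @param form `"coancestry"` or `"kinship"`.
#' @param reference Free-text label naming the ancestral population T.
#' @param check_range Enforce the `[0, 1]` (diagonal `[1/2, 1]` for kinship)
#'   bounds of true parameters. Default `FALSE` (estimates can violate them).
#' @return The matrix with class `"relatedness"` and attributes `form` and
#'   `reference`.
#' @export
relatedness_matrix <- function(values, form = c("coancestry", "kinship"),
                               reference = "MRCA", check_range = FALSE) {
  form <- match.arg(form)
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("`values` must be a square matrix")
  if (!isSymmetric(unname(values), tol = 1e-8))
    stop("`values` must be symmetric")
  if (check_range) {
    d <- diag(values)
    off <- values[row(values) != col(values)]
    if (any(off < 0 | off > 1))
      stop("off-diagonal entries must be in [0, 1]")
    lo <- if (form == "kinship") 0.5 else 0
    if (any(d < lo - 1e-12 | d > 1 + 1e-12))
      stop("diagonal entries out of range for form '", form, "'")
  }
  structure(values, class = c("relatedness", class(values)),
            form = form, reference = reference)
}

#' @export
print.relatedness <- function(x, ...) {
  cat(sprintf("relatedness matrix (%s form, reference: %s), %d x %d\n",
              attr(x, "form"), attr(x, "reference"), nrow(x), ncol(x)))
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  k <- min(6L, nrow(y))
  print(y[seq_len(k), seq_len(k), drop = FALSE], ...)
  if (nrow(y) > k) cat("...\n")
  invisible(x)
}

rel_form <- function(M) {
  f <- attr(M, "form")
  if (is.null(f)) stop("matrix has no `form` attribute; use relatedness_matrix()")
  f
}

#' Convert between kinship and coancestry forms
#'
#' Off-diagonal entries are unchanged; the diagonal is mapped between the
#' inbreeding scale f and the self-kinship scale (1 + f)/2. The conversion
#' is an involution: converting twice returns the input.
#'
#' @param M A [relatedness_matrix()].
#' @param target_form `"coancestry"` or `"kinship"`.
#' @return The converted relatedness matrix.
#' @export
convert_relatedness <- function(M, target_form = c("coancestry", "kinship")) {
  target_form <- match.arg(target_form)
  form <- rel_form(M)
  if (form == target_form) return(M)
  d <- diag(M)
  diag(M) <- if (target_form == "kinship") (1 + d) / 2 else 2 * d - 1
  attr(M, "form") <- target_form
  M
}

#' Weighted summary means of a coancestry matrix
#'
#' For a coancestry matrix \eqn{\Theta} and weights w returns
#' * `theta_bar`: the weighted mean coancestry
#'   \eqn{\bar\theta = \sum_j \sum_k w_j w_k \theta_{jk}},
#' * `theta_bar_j`: the per-individual weighted means
#'   \eqn{\bar\theta_j = \sum_k w_k \theta_{jk}},
#' * `fst`: the generalized F_ST \eqn{\sum_j w_j \theta_{jj}},
#' * `theta_tilde`: the mean *between*-individual coancestry. Under uniform
#'   weights this is \eqn{(n \bar\theta - F_{ST}) / (n - 1)}, the unweighted
#'   mean of the off-diagonal entries. For general weights the weighted
#'   off-diagonal analogue
#'   \eqn{(\bar\theta - \sum_j w_j^2 \theta_{jj}) / (1 - \sum_j w_j^2)}
#'   is used, which reduces exactly to the uniform expression.
#'
#' @param M Coancestry-form [relatedness_matrix()].
#' @param weights Weight vector or `NULL` for uniform.
#' @return List with `theta_bar`, `theta_bar_j`, `theta_tilde`, `fst`.
#' @export
mean_relatedness <- function(M, weights = NULL) {
  if (rel_form(M) != "coancestry")
    stop("`M` must be in coancestry form; see convert_relatedness()")
  n <- nrow(M)
  w <- validate_weights(weights, n)
  theta_bar_j <- as.vector(M %*% w)
  theta_bar <- sum(w * theta_bar_j)
  fst <- sum(w * diag(M))
  w2 <- sum(w^2)
  theta_tilde <- (theta_bar - sum(w^2 * diag(M))) / (1 - w2)
  list(theta_bar = theta_bar, theta_bar_j = theta_bar_j,
       theta_tilde = theta_tilde, fst = fst)
}

#' Bias coefficient of a population structure
#'
#' The bias coefficient \eqn{s^T = \bar\theta^T / F_{ST}} compares the
#' weighted mean coancestry to the weighted mean inbreeding (the generalized
#' F_ST). It quantifies the departure from the independent subpopulations
#' model: s = 1/K for K independent equally-weighted subpopulations, up to
#' s = 1 when all pairs are equally related. It also gives the asymptotic
#' relative bias of the standard-kinship plug-in F_ST estimator when
#' \eqn{F_{ST} \ll 1}.
#'
#' @inheritParams mean_relatedness
#' @return The bias coefficient (scalar in `(0, 1]` for true parameters).
#' @export
bias_coefficient <- function(M, weights = NULL) {
  mm <- mean_relatedness(M, weights)
  if (mm$fst <= 0)
    stop("bias coefficient undefined: weighted mean inbreeding (F_ST) is not > 0")
  mm$theta_bar / mm$fst
}
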
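# Closed-form m -> infinity limits of the analyzed estimators, evaluated
# from true relatedness parameters. These are oracles: they never see
# genotypes, and empirical ratio-of-means estimates converge to them as the
# number of independent loci grows.

#' Limit of the independent-subpopulations F_ST estimator
#'
#' Under arbitrary coancestry, [fst_indep()] converges almost surely to
#' \deqn{\frac{F_{ST} - \tilde\theta}{1 - \tilde\theta},} where
#' \eqn{\tilde\theta = \frac{1}{n(n-1)} \sum_{j \ne k} \theta_{jk}} is the
#' mean between-column coancestry (uniform weights, as the estimator
#' assumes). The limit is invariant to the choice of reference population.
#' It equals F_ST only when \eqn{\tilde\theta = 0} (truly independent
#' subpopulations) and approaches 0 as all pairs become equally related.
#'
#' @param theta Coancestry-form [relatedness_matrix()] of true parameters.
#' @return The limit value (scalar).
#' @export
limit_fst_indep <- function(theta) {
  mm <- mean_relatedness(theta, NULL)
  if (abs(1 - mm$theta_tilde) < 1e-12) stop("mean between coancestry is 1")
  (mm$fst - mm$theta_tilde) / (1 - mm$theta_tilde)
}

#' Limit of the standard kinship estimator
#'
#' The ratio-of-means standard estimator [kinship_std()] converges
#' entrywise to the doubly-centered transformation
#' \deqn{\frac{\phi_{jk} - \bar\phi_j - \bar\phi_k + \bar\phi}{1 - \bar\phi},}
#' with \eqn{\bar\phi_j = \sum_k w_k \phi_{jk}} and
#' \eqn{\bar\phi = \sum_{j,k} w_j w_k \phi_{jk}}. The bias therefore varies
#' per pair of individuals; the weighted row means of the limit matrix are
#' identically zero.
#'
#' @param phi Kinship-form [relatedness_matrix()] of true parameters.
#' @param weights Weight vector used by the estimator (`NULL` = uniform).
#' @return Kinship-form relatedness matrix of limit values (entries may be
#'   negative).
#' @export
limit_kinship_std <- function(phi, weights = NULL) {
  if (rel_form(phi) != "kinship") stop("`phi` must be in kinship form")
  n <- nrow(phi)
  w <- validate_weights(weights, n)
  phi_j <- as.vector(phi %*% w)
  phi_bar <- sum(w * phi_j)
  if (abs(1 - phi_bar) < 1e-12) stop("weighted mean kinship is 1")
  out <- (unclass(phi) - outer(phi_j, phi_j, "+") + phi_bar) / (1 - phi_bar)
  relatedness_matrix(out, form = "kinship")
}

#' Limits of the standard inbreeding estimators
#'
#' Asymptotic values of the three [inbreeding_std()] variants:
#' `"std"`: \eqn{(f_j - 4\bar\phi_j + 3\bar\phi)/(1 - \bar\phi)};
#' `"stdII"`: \eqn{(f_j - \bar\phi)/(1 - \bar\phi)};
#' `"stdIII"`: \eqn{(f_j + \bar\phi - 2\bar\phi_j)/(1 - \bar\phi)}.
#'
#' @inheritParams limit_kinship_std
#' @param variant Which estimator's limit to evaluate.
#' @return Length-n vector of limit values.
#' @export
limit_inbreeding_std <- function(phi, weights = NULL,
                                 variant = c("std", "stdII", "stdIII")) {
  variant <- match.arg(variant)
  if (rel_form(phi) != "kinship") stop("`phi` must be in kinship form")
  n <- nrow(phi)
  w <- validate_weights(weights, n)
  phi_j <- as.vector(phi %*% w)
  phi_bar <- sum(w * phi_j)
  f <- 2 * diag(phi) - 1
  switch(variant,
    std = (f - 4 * phi_j + 3 * phi_bar) / (1 - phi_bar),
    stdII = (f - phi_bar) / (1 - phi_bar),
    stdIII = (f + phi_bar - 2 * phi_j) / (1 - phi_bar)
  )
}

#' Limit of the standard coancestry estimator from IAFs
#'
#' [coancestry_std_iaf()] converges entrywise to
#' \deqn{\frac{\theta_{jk} - \bar\theta_j - \bar\theta_k + \bar\theta}
#'   {1 - \bar\theta},} the same double-centering distortion as for
#' genotypes: access to the latent allele frequencies does not remove the
#' structural bias. The weighted row means of the limit matrix are zero.
#'
#' @param theta Coancestry-form [relatedness_matrix()] of true parameters.
#' @inheritParams limit_kinship_std
#' @return Coancestry-form relatedness matrix of limit values.
#' @export
limit_coancestry_std <- function(theta, weights = NULL) {
  if (rel_form(theta) != "coancestry") stop("`theta` must be in coancestry form")
  n <- nrow(theta)
  w <- validate_weights(weights, n)
  th_j <- as.vector(theta %*% w)
  th_bar <- sum(w * th_j)
  if (abs(1 - th_bar) < 1e-12) stop("weighted mean coancestry is 1")
  out <- (unclass(theta) - outer(th_j, th_j, "+") + th_bar) / (1 - th_bar)
  relatedness_matrix(out, form = "coancestry")
}

#' Limit of the standard plug-in F_ST estimator
#'
#' [fst_std()] converges to \eqn{(F_{ST} - \bar\phi)/(1 - \bar\phi)}
#' (genotypes; \eqn{\bar\theta} for IAFs), equivalently, in terms of the
#' bias coefficient \eqn{s = \bar\phi / F_{ST}},
#' \eqn{F_{ST}(1 - s)/(1 - s F_{ST})}. Supply either `mean_rel` or `s`.
#'
#' @param fst True generalized F_ST.
#' @param mean_rel True weighted mean kinship/coancestry
#'   (\eqn{\bar\phi} or \eqn{\bar\theta}).
#' @param s Bias coefficient; used if `mean_rel` is `NULL`.
#' @return The limit value (scalar).
#' @export
limit_fst_std <- function(fst, mean_rel = NULL, s = NULL) {
  if (is.null(mean_rel)) {
    if (is.null(s)) stop("supply `mean_rel` or `s`")
    mean_rel <- s * fst
  }
  if (abs(1 - mean_rel) < 1e-12) stop("mean relatedness is 1")
  (fst - mean_rel) / (1 - mean_rel)
}

#' Limit of the Weir-Goudet individual kinship estimator
#'
#' [kinship_wg()] converges entrywise to
#' \eqn{(\phi_{jk} - \tilde\phi)/(1 - \tilde\phi)} where \eqn{\tilde\phi}
#' is the *unweighted* mean kinship over unordered pairs j != k. This
#' recovers the IBD probabilities if and only if \eqn{\tilde\phi = 0}.
#'
#' @inheritParams limit_kinship_std
#' @return Kinship-form relatedness matrix of limit values.
#' @export
limit_kinship_wg <- function(phi) {
  if (rel_form(phi) != "kinship") stop("`phi` must be in kinship form")
  phi_tilde <- mean(phi[upper.tri(phi)])
  if (abs(1 - phi_tilde) < 1e-12) stop("mean pair kinship is 1")
  out <- (unclass(phi) - phi_tilde) / (1 - phi_tilde)
  relatedness_matrix(out, form = "kinship")
}

#' Asymptotic relative error of the standard plug-in F_ST
#'
#' The relative error \eqn{1 - \hat F_{ST}^{std} / F_{ST}} converges to
#' \eqn{s (1 - F_{ST}) / (1 - s F_{ST})}, which is approximately the bias
#' coefficient s itself when \eqn{F_{ST} \ll 1} (hence its name).
#'
#' @param fst True generalized F_ST.
#' @param s Bias coefficient.
#' @return The limiting relative error (scalar).
#' @export
relative_error_fst_std <- function(fst, s) {
  s * (1 - fst) / (1 - s * fst)
}
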
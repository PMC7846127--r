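# Replicate experiments, RMSE summaries relative to the mean kinship, and
# order-statistic prediction intervals.

to_coancestry_scale <- function(M) {
  if (inherits(M, "relatedness") && rel_form(M) == "kinship")
    M <- convert_relatedness(M, "coancestry")
  unclass(M)
}

#' RMSE of a relatedness estimate relative to the mean kinship
#'
#' Root-mean-square error between an estimated and a reference relatedness
#' matrix, expressed as a percentage of a mean-kinship scale:
#' \eqn{100 \cdot \sqrt{mean((est - ref)^2)} / \bar\phi}. Entries compared
#' are the unique off-diagonal pairs (j < k) plus, when
#' `include_diagonal = TRUE`, the diagonal on the *inbreeding* scale
#' (kinship-form diagonals are mapped via \eqn{2\phi_{jj} - 1} so that
#' self terms are commensurate with between-individual kinship, matching
#' how such matrices are usually plotted).
#'
#' @param est,ref [relatedness_matrix()] objects (any form) or plain
#'   matrices already on the coancestry scale; same dimensions.
#' @param phi_mean Positive scale, typically the mean of the true
#'   coancestry-scale matrix.
#' @param include_diagonal Include the inbreeding-scale diagonal entries.
#' @return RMSE as a percentage of `phi_mean`.
#' @export
rmse_relative <- function(est, ref, phi_mean, include_diagonal = TRUE) {
  if (!all(dim(est) == dim(ref))) stop("`est` and `ref` must have equal dims")
  if (!is.numeric(phi_mean) || phi_mean <= 0) stop("`phi_mean` must be > 0")
  err <- to_coancestry_scale(est) - to_coancestry_scale(ref)
  vals <- err[upper.tri(err)]
  if (include_diagonal) vals <- c(vals, diag(err))
  100 * sqrt(mean(vals^2)) / phi_mean
}

#' Order-statistic prediction interval
#'
#' For R independent replicate statistics, the interval between the j-th
#' smallest and j-th largest values, \eqn{[X_{(j)}, X_{(R+1-j)}]}, is a
#' prediction interval for the next draw with confidence
#' \eqn{(R + 1 - 2j) / (R + 1)}. With R = 39 and j = 1 (the full range)
#' the confidence is exactly 95%.
#'
#' @param values Length-R numeric vector of replicate statistics.
#' @param j Order-statistic depth (`R >= 2j`).
#' @return List with `lo`, `hi` and `confidence`.
#' @export
prediction_interval <- function(values, j = 1L) {
  R <- length(values)
  if (R < 2 * j) stop("need at least 2j replicates")
  s <- sort(values)
  list(lo = s[j], hi = s[R + 1 - j], confidence = (R + 1 - 2 * j) / (R + 1))
}

# F_ST estimates for one simulated dataset; A statistic shared across methods
fst_methods_on_sim <- function(sim, methods) {
  A <- NULL
  need_a <- any(methods %in% c("new", "wg"))
  if (need_a) A <- a_statistic(sim$X)
  vapply(methods, function(mth) {
    switch(mth,
      wc = fst_wc(sim$X, sim$labels)$value,
      weir_hill = fst_weir_hill(sim$X, sim$labels)$value,
      hudson_k = fst_hudson_k(sim$X, sim$labels)$value,
      std = fst_std(sim$X, sim$weights)$value,
      indep_iaf = fst_indep(sim$iafs)$value,
      new = {
        amin <- a_min_subpops(A, sim$labels)
        fst_new(kinship_new(A, amin), sim$weights)$value
      },
      wg = fst_wg_individuals(kinship_wg(A))$value,
      stop("unknown method: ", mth)
    )
  }, numeric(1))
}

#' Replicate F_ST estimation experiments
#'
#' Repeats a simulation R times with the population structure held fixed
#' (subpopulation sizes or admixture proportions drawn once from the master
#' seed) while ancestral/subpopulation frequencies and genotypes are drawn
#' fresh each replicate, and computes the requested F_ST estimators on each
#' replicate. Sub-seeds are derived from the master seed so every replicate
#' is reproducible.
#'
#' @param config List with `model` (`"indep"` or `"admix"`), `n`, `m`, `K`,
#'   `fst`, and for the admixture model `s_target`.
#' @param methods Character vector among `"wc"`, `"weir_hill"`,
#'   `"hudson_k"`, `"std"`, `"new"`, `"wg"`, `"indep_iaf"`.
#' @param R Number of replicates (default 39: the full range of 39
#'   replicates is a 95% prediction interval).
#' @param seed Master seed.
#' @return Tidy data.frame with columns `replicate`, `method`, `estimate`.
#' @export
replicate_experiment <- function(config, methods = c("hudson_k", "new"),
                                 R = 39L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- match.arg(config$model, c("indep", "admix"))
  sub_seeds <- sample.int(.Machine$integer.max, R)
  # fix the structure across replicates
  sizes <- if (model == "indep") random_subpop_sizes(config$n, config$K)
  sigma <- if (model == "admix")
    solve_sigma(config$s_target, config$n, config$K)
  out <- vector("list", R)
  for (r in seq_len(R)) {
    set.seed(sub_seeds[r])
    sim <- if (model == "indep") {
      simulate_indep(config$n, config$m, config$K, config$fst, sizes = sizes)
    } else {
      simulate_admix(config$n, config$m, config$K, config$fst,
                     sigma = sigma)
    }
    est <- fst_methods_on_sim(sim, methods)
    out[[r]] <- data.frame(replicate = r, method = methods,
                           estimate = unname(est))
  }
  do.call(rbind, out)
}

#' Kinship estimator accuracy study on the admixture model
#'
#' Runs the full admixture-model kinship evaluation at a chosen scale
#' (defaults: n = 1000 individuals, m = 300,000 loci, K = 10,
#' F_ST = 0.1, bias coefficient 1/2) without ever materializing the whole
#' genotype or IAF matrix: loci are generated and accumulated in blocks,
#' so memory stays bounded by `block_size` x n. Computes
#' * the new kinship estimator (A statistic + minimum between the
#'   K geographic clusters),
#' * the standard estimator in both ratio-of-means and mean-of-ratios
#'   forms (uniform weights),
#' * the standard coancestry estimator from the latent IAFs,
#' and summarizes each with [rmse_relative()] against the true matrix or
#' the corresponding asymptotic limit, on the scale of the mean true
#' coancestry.
#'
#' @inheritParams simulate_admix
#' @param block_size Loci per accumulation block.
#' @param include_matrices Also return the estimated matrices.
#' @param include_genotypes Also return the generated genotype and IAF
#'   matrices (only sensible at small scales; defeats the purpose of
#'   blocking at full scale).
#' @return List with the RMSE percentages (`rmse_new_truth`,
#'   `rmse_std_truth`, `rmse_rom_limit`, `rmse_mor_limit`,
#'   `rmse_iaf_limit`), the calibration (`sigma`, `tau`, `a_min`,
#'   `phi_mean`), and the F_ST estimates `fst_new` and `fst_std`.
#' @export
kinship_accuracy_admix <- function(n = 1000, m = 300000, K = 10, fst = 0.1,
                                   s_target = 0.5, sigma = NULL,
                                   freq_range = c(0.01, 0.5),
                                   block_size = 10000L, seed = NULL,
                                   include_matrices = FALSE,
                                   include_genotypes = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma)) sigma <- solve_sigma(s_target, n, K)
  Q <- admix_props_1d(n, K, sigma)
  tau <- tau_admix(fst, Q)
  f_inter <- f_intermediate(K, tau)
  nu <- 1 / f_inter - 1
  theta_true <- true_coancestry_admix(Q, f_inter)
  phi_true <- convert_relatedness(theta_true, "kinship")
  labels <- assign_subpops_1d(n, K)

  C_std <- C_mor <- C_a <- C_iaf <- matrix(0, n, n)
  D_std <- D_iaf <- 0
  m_mor <- 0L
  X_blocks <- if (include_genotypes) list()
  P_blocks <- if (include_genotypes) list()
  tQ <- t(Q)
  for (idx in row_blocks(m, block_size)) {
    mb <- length(idx)
    p_anc <- stats::runif(mb, freq_range[1], freq_range[2])
    P_sub <- vapply(seq_len(K), function(u)
      stats::rbeta(mb, p_anc * nu[u], (1 - p_anc) * nu[u]), numeric(mb))
    dim(P_sub) <- c(mb, K)
    Pi <- P_sub %*% tQ
    Pi[Pi < 0] <- 0; Pi[Pi > 1] <- 1
    Xb <- stats::rbinom(mb * n, 2L, Pi)
    dim(Xb) <- c(mb, n)
    # standard (ratio-of-means) + A statistic share the genotype block
    p_hat <- rowMeans(Xb) / 2
    C_std <- C_std + crossprod(Xb - 2 * p_hat)
    D_std <- D_std + sum(p_hat * (1 - p_hat))
    C_a <- C_a + crossprod(Xb - 1)
    keep <- p_hat > 0 & p_hat < 1
    if (any(keep)) {
      Xs <- (Xb[keep, , drop = FALSE] - 2 * p_hat[keep]) /
        (2 * sqrt(p_hat[keep] * (1 - p_hat[keep])))
      C_mor <- C_mor + crossprod(Xs)
      m_mor <- m_mor + sum(keep)
    }
    p_iaf <- rowMeans(Pi)
    C_iaf <- C_iaf + crossprod(Pi - p_iaf)
    D_iaf <- D_iaf + sum(p_iaf * (1 - p_iaf))
    if (include_genotypes) {
      X_blocks[[length(X_blocks) + 1L]] <- Xb
      P_blocks[[length(P_blocks) + 1L]] <- Pi
    }
  }

  K_rom <- relatedness_matrix(C_std / (4 * D_std), form = "kinship")
  K_mor <- relatedness_matrix(C_mor / m_mor, form = "kinship")
  A <- C_a / m - 1
  a_min <- a_min_subpops(A, labels)
  K_new <- kinship_new(A, a_min)
  Th_iaf <- relatedness_matrix(C_iaf / D_iaf, form = "coancestry")

  L_kin <- limit_kinship_std(phi_true)
  L_coan <- limit_coancestry_std(theta_true)
  phi_mean <- mean(theta_true)

  out <- list(
    rmse_new_truth = rmse_relative(K_new, phi_true, phi_mean),
    rmse_std_truth = rmse_relative(K_rom, phi_true, phi_mean),
    rmse_rom_limit = rmse_relative(K_rom, L_kin, phi_mean),
    rmse_mor_limit = rmse_relative(K_mor, L_kin, phi_mean),
    rmse_iaf_limit = rmse_relative(Th_iaf, L_coan, phi_mean),
    fst_new = fst_new(K_new)$value,
    fst_std = mean(2 * diag(K_rom) - 1),
    sigma = sigma, tau = tau, a_min = a_min, phi_mean = phi_mean,
    n = n, m = m, K = K
  )
  if (include_matrices)
    out <- c(out, list(kinship_new = K_new, kinship_std = K_rom,
                       kinship_std_mor = K_mor, coancestry_iaf = Th_iaf,
                       theta_true = theta_true, limit_std = L_kin,
                       limit_iaf = L_coan, A = A, labels = labels))
  if (include_genotypes)
    out <- c(out, list(X = do.call(rbind, X_blocks),
                       iafs = do.call(rbind, P_blocks)))
  out
}
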
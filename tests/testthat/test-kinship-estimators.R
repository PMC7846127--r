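test_that("estimate_freqs averages dosages and IAFs with weights", {
  X <- matrix(c(0L, 2L,
                1L, 1L), nrow = 2, byrow = TRUE)
  expect_equal(estimate_freqs(X), c(0.5, 0.5))
  expect_equal(estimate_freqs(X, c(0.25, 0.75))[1], 0.75)
  P <- matrix(c(0.2, 0.6), 1)
  expect_equal(estimate_freqs(P, input = "iafs"), 0.4)
  expect_error(estimate_freqs(X, c(0, 1)), "positive")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(estimate_freqs(Xna), "missing")
})

test_that("kinship_std matches the hand-computed 2x2 case", {
  # two individuals, two loci with opposite homozygotes:
  # p_hat = (1/2, 1/2), numerator_12 = -2, denominator = 2
  X <- matrix(c(0L, 2L,
                2L, 0L), nrow = 2, byrow = TRUE)
  K <- kinship_std(X)
  expect_equal(K[1, 2], -1)
  expect_equal(attr(K, "form"), "kinship")
  # all-heterozygote matrix is degenerate: p_hat = 1/2 but every (x - 2p) = 0
  # numerator and denominator both informative-free at a single locus of 1s
  Xh <- matrix(1L, 3, 2)
  expect_error(kinship_std(cbind(Xh) * 0L + 2L), "monomorphic")
})

test_that("mean_of_ratios skips fixed loci and both forms approach the limit", {
  set.seed(5)
  sim <- simulate_admix(n = 40, m = 30000, K = 4, fst = 0.1, s_target = 0.5)
  K_rom <- kinship_std(sim$X)
  suppressMessages(K_mor <- kinship_std(sim$X, form = "mean_of_ratios"))
  L <- limit_kinship_std(convert_relatedness(sim$theta, "kinship"))
  phi_mean <- mean(sim$theta)
  r_rom <- rmse_relative(K_rom, L, phi_mean)
  r_mor <- rmse_relative(K_mor, L, phi_mean)
  # ratio-of-means sits strictly closer to the asymptotic limit
  expect_lt(r_rom, r_mor)
  expect_lt(r_rom, 35) # sampling error at m = 30k, small n
})

test_that("inbreeding_std variants behave as derived", {
  set.seed(9)
  sim <- simulate_indep(n = 30, m = 500, K = 3, fst = 0.15)
  X <- sim$X
  # fully homozygous individual: stdII heterozygosity-deficit estimate is 1
  Xhom <- X
  Xhom[, 1] <- ifelse(X[, 1] >= 1L, 2L, 0L)
  expect_equal(inbreeding_std(Xhom, variant = "stdII")[1], 1)
  # fully heterozygous individual: closed form 1 - m / (2 sum p(1-p))
  Xhet <- X
  Xhet[, 2] <- 1L
  p <- estimate_freqs(Xhet)
  expect_equal(inbreeding_std(Xhet, variant = "stdII")[2],
               1 - nrow(X) / (2 * sum(p * (1 - p))))
  # std variant equals the diagonal route through kinship_std
  expect_equal(inbreeding_std(X, variant = "std"),
               2 * diag(kinship_std(X)) - 1)
})

test_that("the three inbreeding variants give one identical plug-in F_ST", {
  set.seed(31)
  sim <- simulate_admix(n = 25, m = 800, K = 3, fst = 0.1, s_target = 0.5)
  w <- rgamma(25, 1); w <- w / sum(w)
  plugin <- vapply(c("std", "stdII", "stdIII"), function(v)
    sum(w * inbreeding_std(sim$X, w, variant = v)), numeric(1))
  expect_equal(plugin[["stdII"]], plugin[["std"]], tolerance = 1e-12)
  expect_equal(plugin[["stdIII"]], plugin[["std"]], tolerance = 1e-12)
  expect_equal(fst_std(sim$X, w)$value, plugin[["std"]], tolerance = 1e-12)
})

test_that("a_statistic matches hand values and respects dosage bounds", {
  # opposite homozygotes at both loci: mean((x-1)(x-1)) - 1 = -1 - 1 = -2
  X <- matrix(c(0L, 2L,
                2L, 0L), nrow = 2, byrow = TRUE)
  A <- a_statistic(X)
  expect_equal(A[1, 2], -2)
  expect_equal(A[1, 1], 0) # self: mean(1, 1) - 1
  # all-heterozygote pair: products all zero
  expect_equal(a_statistic(matrix(1L, 5, 2))[1, 2], -1)
  expect_equal(attr(A, "m_loci"), 2L)
  # algebraic bounds on arbitrary dosage data
  set.seed(3)
  Xr <- matrix(sample(0:2, 600, replace = TRUE), 60, 10)
  Ar <- a_statistic(Xr)
  expect_true(all(Ar >= -2 & Ar <= 0))
})

test_that("A statistic is unbiased for (phi - 1) times the nuisance scale", {
  # Monte-Carlo moment check at fixed IAFs: E[A_jk] = (phi_jk - 1) v_m
  set.seed(17)
  m <- 300; n <- 4
  Q <- matrix(rgamma(n * 3, 1), n); Q <- Q / rowSums(Q)
  f <- c(0.1, 0.2, 0.3)
  theta <- true_coancestry_admix(Q, f)
  p_anc <- draw_ancestral_freqs(m)
  P_sub <- vapply(f, function(fu) draw_bn_freqs(p_anc, fu), numeric(m))
  P <- draw_iafs(P_sub, Q)
  R <- 400
  a12 <- replicate(R, a_statistic(draw_genotypes(P))[1, 2])
  # conditional on the IAFs the expectation uses the realized frequencies:
  # E[(x1-1)(x2-1)] = (2 pi1 - 1)(2 pi2 - 1) per locus
  expected <- mean((2 * P[, 1] - 1) * (2 * P[, 2] - 1)) - 1
  se <- sd(a12) / sqrt(R)
  expect_lt(abs(mean(a12) - expected), 3 * se + 1e-12)
  # marginally over frequency draws this equals (phi_12 - 1) * v_m, checked
  # at coarse Monte-Carlo precision over fresh frequency draws
  reps <- replicate(150, {
    p_anc <- draw_ancestral_freqs(m)
    P_sub <- vapply(f, function(fu) draw_bn_freqs(p_anc, fu), numeric(m))
    P <- draw_iafs(P_sub, Q)
    c(a_statistic(draw_genotypes(P))[1, 2], 4 * mean(p_anc * (1 - p_anc)))
  })
  expected_marginal <- (theta[1, 2] - 1) * mean(reps[2, ])
  se_marginal <- sd(reps[1, ]) / sqrt(ncol(reps))
  expect_lt(abs(mean(reps[1, ]) - expected_marginal), 3 * se_marginal)
})

test_that("estimated ancestral frequencies have structure-limited variance", {
  # Var(p_hat_i) = p_i (1 - p_i) phi_bar: the estimator is unbiased but not
  # consistent under structure
  set.seed(23)
  n <- 40; K <- 3
  Q <- matrix(rgamma(n * K, 1), n); Q <- Q / rowSums(Q)
  f <- c(0.15, 0.3, 0.45)
  theta <- true_coancestry_admix(Q, f)
  phi <- convert_relatedness(theta, "kinship")
  w <- uniform_weights(n)
  phi_bar <- sum(outer(w, w) * unclass(phi))
  p_i <- 0.3
  R <- 3000
  p_hats <- replicate(R, {
    P_sub <- vapply(f, function(fu) draw_bn_freqs(p_i, fu), numeric(1))
    P <- draw_iafs(matrix(P_sub, 1), Q)
    estimate_freqs(draw_genotypes(P))
  })
  v_expected <- p_i * (1 - p_i) * phi_bar
  # variance of a variance estimate: allow a generous Monte-Carlo band
  expect_equal(var(as.vector(p_hats)), v_expected, tolerance = 0.1)
})

test_that("a_min_subpops takes the minimum between-block mean", {
  # three blocks engineered so between-block means are -0.4, -0.2, -0.3
  A <- matrix(0, 6, 6)
  blocks <- list(1:2, 3:4, 5:6)
  fill <- function(A, bi, bj, v) { A[blocks[[bi]], blocks[[bj]]] <- v
                                   A[blocks[[bj]], blocks[[bi]]] <- v; A }
  A <- fill(A, 1, 2, -0.4); A <- fill(A, 1, 3, -0.2); A <- fill(A, 2, 3, -0.3)
  labels <- rep(1:3, each = 2)
  expect_equal(a_min_subpops(A, labels), -0.4)
  # brute force over the three block pairs agrees
  brute <- min(sapply(list(c(1, 2), c(1, 3), c(2, 3)), function(uv)
    mean(A[blocks[[uv[1]]], blocks[[uv[2]]]])))
  expect_equal(a_min_subpops(A, labels), brute)
  # K = 2: the single between-block mean
  expect_equal(a_min_subpops(A, rep(1:2, c(2, 4))),
               mean(A[1:2, 3:6]))
  # singleton blocks: min over individual off-diagonal entries across blocks
  expect_equal(a_min_subpops(A, 1:6), min(A[upper.tri(A)]))
  expect_error(a_min_subpops(A, rep(1, 6)), "2 subpopulations")
})

test_that("kinship_new rescales by the minimum and validates it", {
  A <- matrix(c(-0.3, -0.5, -0.5, -0.1), 2)
  K <- kinship_new(A, -0.8)
  expect_equal(K[1, 2], 0.375)  # 1 - (-0.5)/(-0.8)
  expect_equal(kinship_new(A, -0.3)[1, 1], 0) # least related maps to zero
  expect_equal(kinship_new(matrix(0, 2, 2), -0.4)[1, 2], 1)
  expect_error(kinship_new(A, 0.1), "negative")
  expect_error(kinship_new(A, 0), "negative")
  # inbreeding transform
  Kd <- relatedness_matrix(diag(c(0.55, 1)) + 0.1 - diag(0.1, 2), "kinship")
  expect_equal(inbreeding_new(Kd), c(0.1, 1))
})

test_that("kinship_new recovers the truth on simulated admixture data", {
  set.seed(41)
  sims <- lapply(c(2000, 40000), function(m)
    simulate_admix(n = 50, m = m, K = 5, fst = 0.1, s_target = 0.5))
  phi_mean <- mean(sims[[1]]$theta)
  rmses <- vapply(sims, function(sim) {
    A <- a_statistic(sim$X)
    K <- kinship_new(A, a_min_subpops(A, sim$labels))
    rmse_relative(K, convert_relatedness(sim$theta, "kinship"), phi_mean)
  }, numeric(1))
  # consistency: error shrinks as loci accumulate
  expect_lt(rmses[2], rmses[1])
  expect_lt(rmses[2], 30)
})

test_that("kinship_wg rescales by the average and matches its limit role", {
  A <- matrix(c(-0.4, -0.2, -0.3,
                -0.2, -0.5, -0.6,
                -0.3, -0.6, -0.1), 3)
  a_avg <- mean(A[upper.tri(A)])
  W <- kinship_wg(A)
  expect_equal(W[1, 2], 1 - A[1, 2] / a_avg)
  # a pair sitting exactly at the average maps to zero kinship
  A2 <- A
  A2[1, 3] <- A2[3, 1] <- mean(A2[cbind(c(1, 2), c(2, 3))])
  expect_equal(kinship_wg(A2)[1, 3], 0)
  # unstructured data: WG recovers kinship (phi_tilde = 0)
  set.seed(13)
  P <- matrix(runif(4000, 0.2, 0.8), 1000, 4)[, rep(1, 4)] # identical IAFs
  X <- draw_genotypes(P)
  Wu <- kinship_wg(a_statistic(X))
  expect_true(all(abs(Wu[upper.tri(Wu)]) < 0.2)) # zero kinship, MC noise
})

test_that("coancestry_std_iaf matches hand cases and its limit", {
  # identical IAF rows across individuals: zero matrix
  P <- matrix(rep(c(0.2, 0.5, 0.7), 3), 3, 3)
  expect_true(all(abs(coancestry_std_iaf(P)) < 1e-12))
  # one locus, two "subpopulations" fixed for opposite alleles
  P2 <- matrix(c(0, 1), 1, 2)
  Th <- coancestry_std_iaf(P2)
  expect_equal(unclass(Th), matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  # large-m admixture: close to the double-centered limit
  set.seed(29)
  sim <- simulate_admix(n = 30, m = 50000, K = 3, fst = 0.1, s_target = 0.5)
  Th3 <- coancestry_std_iaf(sim$iafs)
  L <- limit_coancestry_std(sim$theta)
  expect_lt(rmse_relative(Th3, L, mean(sim$theta)), 5)
})
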
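test_that("ancestral frequency draws respect the range", {
  set.seed(1)
  p <- draw_ancestral_freqs(5000)
  expect_true(all(p >= 0.01 & p <= 0.5))
  expect_equal(mean(p), 0.255, tolerance = 0.01)
  set.seed(3); p1 <- draw_ancestral_freqs(100)
  set.seed(3); p2 <- draw_ancestral_freqs(100)
  expect_identical(p1, p2)
  expect_error(draw_ancestral_freqs(10, c(0.5, 0.2)), "range")
})

test_that("Balding-Nichols draws have the coancestry-model moments", {
  set.seed(6)
  p <- 0.3; f <- 0.2
  x <- draw_bn_freqs(rep(p, 50000), f)
  expect_true(all(x >= 0 & x <= 1))
  expect_equal(mean(x), p, tolerance = 0.01)
  expect_equal(var(x), f * p * (1 - p), tolerance = 0.01)
  # degenerate no-drift limit returns the ancestral frequency exactly
  expect_identical(draw_bn_freqs(c(0.2, 0.4), 0), c(0.2, 0.4))
  expect_error(draw_bn_freqs(0.3, 1), "f")
})

test_that("random subpopulation sizes sum to n with the minimum enforced", {
  set.seed(12)
  for (i in 1:10) {
    r <- random_subpop_sizes(1000, 10)
    expect_equal(sum(r), 1000)
    expect_length(r, 10)
  }
  # the redraw loop targets min >= n/(3K); the +/-1 repair can nudge by one
  r <- random_subpop_sizes(300, 5)
  expect_gte(min(r), 300 / 15 - 1)
  expect_identical(random_subpop_sizes(50, 1), 50)
  expect_error(random_subpop_sizes(10, 5), "3K")
})

test_that("tau_indep matches the closed form and flags infeasible targets", {
  expect_equal(tau_indep(0.1, 10), 2 / 11)
  expect_equal(round(tau_indep(0.1, 10), 2), 0.18)
  # boundary: F_ST = 0.55 with K = 10 gives tau exactly 1
  expect_equal(tau_indep(0.55, 10), 1)
  expect_error(tau_indep(0.56, 10), "infeasible")
  expect_equal(tau_indep(0.3, 1), 0.3)
})

test_that("admixture proportions follow the 1D geography", {
  Q <- admix_props_1d(100, 5, 1.5)
  expect_equal(rowSums(Q), rep(1, 100))
  expect_true(all(Q >= 0))
  # reflection symmetry of the grid: individual j mirrors individual n+1-j
  expect_equal(Q, Q[100:1, 5:1], ignore_attr = TRUE)
  # sigma -> 0 degenerates to one-hot assignment to the nearest subpopulation
  Q0 <- admix_props_1d(100, 5, 1e-8)
  expect_equal(unname(Q0[cbind(1:100, assign_subpops_1d(100, 5))]),
               rep(1, 100))
  # single individual sits at the midpoint: symmetric ancestry
  Q1 <- admix_props_1d(1, 4, 2)
  expect_equal(Q1[1, ], Q1[1, 4:1])
  expect_error(admix_props_1d(10, 3, 0), "sigma")
})

test_that("geographic clustering is balanced on the standard grid", {
  u <- assign_subpops_1d(1000, 10)
  expect_equal(as.vector(table(u)), rep(100L, 10))
  # n = K grid: identity assignment
  expect_equal(assign_subpops_1d(10, 10), 1:10)
  # exact midpoint ties go to the lower index
  expect_equal(kinfst:::nearest_subpop(2.5, 5), 2L)
})

test_that("solve_sigma and tau_admix reproduce the calibrated scenario", {
  sig <- solve_sigma(0.5, 1000, 10)
  expect_equal(sig, 1.78, tolerance = 0.01)
  Q <- admix_props_1d(1000, 10, sig)
  tau <- tau_admix(0.1, Q)
  expect_equal(tau, 0.901, tolerance = 0.005)
  # the bias coefficient is monotone in sigma on the bracket
  s_vals <- vapply(c(0.5, 1, 2, 4), kinfst:::bias_coefficient_sigma,
                   numeric(1), n = 200, K = 10)
  expect_true(all(diff(s_vals) > 0))
  # tiny sigma approaches the independent-blocks value 1/K
  expect_equal(kinfst:::bias_coefficient_sigma(0.01, 200, 10), 0.1,
               tolerance = 1e-6)
  expect_error(solve_sigma(0.05, 100, 10), "s_target")
})

test_that("one-hot admixture reduces tau_admix to the independent closed form", {
  K <- 6; n <- 60
  Q <- diag(K)[rep(1:K, each = n / K), ]
  expect_equal(tau_admix(0.1, Q), tau_indep(0.1, K), tolerance = 1e-12)
  expect_equal(tau_admix(0, admix_props_1d(50, 5, 1)), 0)
})

test_that("true admixture coancestry has the designed F_ST and bias coefficient", {
  sig <- solve_sigma(0.5, 500, 10)
  Q <- admix_props_1d(500, 10, sig)
  f <- f_intermediate(10, tau_admix(0.1, Q))
  Th <- true_coancestry_admix(Q, f)
  expect_equal(mean_relatedness(Th)$fst, 0.1, tolerance = 1e-9)
  expect_equal(bias_coefficient(Th), 0.5, tolerance = 1e-9)
  # identity admixture rows: coancestry is just diag(f)
  expect_equal(unclass(true_coancestry_admix(diag(3), c(0.1, 0.2, 0.3))),
               diag(c(0.1, 0.2, 0.3)), ignore_attr = TRUE)
  # positive semidefiniteness of the quadratic form
  ev <- eigen(unclass(Th), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("IAFs and genotypes obey the model moments", {
  set.seed(26)
  # pi = 0 forces x = 0
  expect_true(all(draw_genotypes(matrix(0, 5, 3)) == 0))
  # mean dosage ~ 2 pi
  P <- matrix(runif(20, 0.2, 0.8), 1, 20)[rep(1, 1), , drop = FALSE]
  X <- replicate(2000, draw_genotypes(P)[1, ])
  expect_equal(rowMeans(X), 2 * P[1, ], tolerance = 0.05)
  # genotype covariance across individuals matches 4p(1-p) theta; loci are
  # iid replicates at a fixed ancestral frequency
  n <- 30; m <- 50000
  Q <- admix_props_1d(n, 3, 1)
  f <- c(0.1, 0.2, 0.3)
  Th <- true_coancestry_admix(Q, f)
  p_anc <- rep(0.4, m)
  P_sub <- vapply(f, function(fu) draw_bn_freqs(p_anc, fu), numeric(m))
  Xc <- draw_genotypes(draw_iafs(P_sub, Q))
  expect_equal(cov(Xc[, 1], Xc[, 2]), 4 * 0.4 * 0.6 * Th[1, 2],
               tolerance = 0.15)
})

test_that("simulate_indep builds the block world with balanced weights", {
  set.seed(33)
  sim <- simulate_indep(n = 90, m = 200, K = 3, fst = 0.12)
  expect_equal(dim(sim$X), c(200L, 90L))
  expect_true(all(sim$X %in% 0:2))
  # off-diagonal blocks of the true coancestry are exactly zero
  Th <- unclass(sim$theta)
  off_block <- Th[sim$labels == 1, sim$labels == 2]
  expect_true(all(off_block == 0))
  # generalized F_ST equals the target and s = 1/K exactly
  expect_equal(sum(sim$weights * diag(Th)), 0.12, tolerance = 1e-12)
  expect_equal(bias_coefficient(sim$theta, sim$weights), 1 / 3,
               tolerance = 1e-12)
  expect_equal(sum(sim$weights), 1)
  # reproducible under a fixed seed
  s1 <- simulate_indep(n = 30, m = 50, K = 2, fst = 0.1, seed = 99)
  s2 <- simulate_indep(n = 30, m = 50, K = 2, fst = 0.1, seed = 99)
  expect_identical(s1$X, s2$X)
})

test_that("simulate_admix carries its calibration in the bundle", {
  set.seed(37)
  sim <- simulate_admix(n = 60, m = 100, K = 4, fst = 0.1, s_target = 0.4)
  expect_equal(rowSums(sim$Q), rep(1, 60))
  expect_equal(mean_relatedness(sim$theta)$fst, 0.1, tolerance = 1e-9)
  expect_equal(bias_coefficient(sim$theta), 0.4, tolerance = 1e-8)
  expect_equal(dim(sim$iafs), c(100L, 60L))
  expect_true(all(sim$iafs >= 0 & sim$iafs <= 1))
  expect_equal(sort(unique(sim$labels)), 1:4)
})
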
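# Small fixtures built in code, shared across test files.

# block-constant coancestry matrix of K independent subpopulations:
# theta_jk = f_u within subpopulation u (including the diagonal), 0 between
block_coancestry <- function(sizes, f) {
  labels <- rep(seq_along(sizes), sizes)
  Q <- diag(length(sizes))[labels, , drop = FALSE]
  relatedness_matrix(Q %*% (f * t(Q)), form = "coancestry")
}

# tiny deterministic dosage matrix, loci x individuals
toy_genotypes <- function() {
  # 4 loci x 3 individuals, all loci polymorphic under uniform weights
  matrix(c(0L, 2L, 1L,
           2L, 0L, 1L,
           1L, 1L, 0L,
           2L, 2L, 1L), nrow = 4, byrow = TRUE)
}

# random valid coancestry matrix via a random admixture model
random_coancestry <- function(n, K = 3, fst = 0.2) {
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  f <- seq_len(K) / K * tau_admix(fst, Q)
  true_coancestry_admix(Q, f)
}
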
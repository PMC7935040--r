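test_that("normalization schemes stabilize the adjacency", {
  A <- matrix(c(0, 1, 1, 0), 2)
  S <- normalize_adjacency(A, "singular_value")
  expect_equal(S$normalization_factor, 2)   # sigma_max = 1
  expect_equal(S$A_norm, A / 2)
  expect_equal(max(abs(eigen(S$A_norm)$values)), 0.5)

  S0 <- normalize_adjacency(matrix(0, 3, 3))
  expect_equal(S0$normalization_factor, 1)
  expect_equal(S0$A_norm, matrix(0, 3, 3))

  set.seed(5)
  w <- random_sym_graph(10, density = 0.6, seed = 5)
  for (scheme in c("singular_value", "spectral_radius")) {
    S <- normalize_adjacency(w, scheme)
    expect_lt(max(Mod(eigen(S$A_norm)$values)), 1)
  }
  expect_error(normalize_adjacency(matrix(c(0, Inf, Inf, 0), 2)),
               "non-finite")
})

test_that("the Gramian solves the stationary equation and matches examples", {
  # 1x1, a = 0: only the i = 0 term survives
  expect_equal(controllability_gramian(normalized_system_raw(matrix(0, 1, 1)), 1),
               matrix(1, 1, 1))
  # 1x1, a = 0.5: geometric series 1/(1 - a^2)
  expect_equal(controllability_gramian(normalized_system_raw(matrix(0.5, 1, 1)), 1),
               matrix(4 / 3, 1, 1), tolerance = 1e-12)
  # 2x2 coupling example: W = (16/15) diag(1, 1/4)
  A <- matrix(c(0, 0.5, 0.5, 0), 2)
  W <- controllability_gramian(normalized_system_raw(A), 1)
  expect_equal(W, (16 / 15) * diag(c(1, 0.25)), tolerance = 1e-12)
  # stationarity: W = A W A' + B B'
  B <- matrix(c(1, 0), 2, 1)
  expect_equal(W, A %*% W %*% t(A) + B %*% t(B), tolerance = 1e-12)
  # PSD within tolerance
  expect_true(all(eigen(W, symmetric = TRUE)$values > -1e-10))
  # divergence error names the radius
  expect_error(controllability_gramian(normalized_system_raw(diag(2)), 1),
               "spectral radius 1")
})

test_that("average controllability equals the Gramian trace", {
  expect_equal(average_controllability(normalized_system_raw(matrix(0.5, 1, 1))),
               4 / 3, tolerance = 1e-12)
  A <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(unname(average_controllability(normalized_system_raw(A))),
               c(4 / 3, 4 / 3), tolerance = 1e-12)
  expect_equal(unname(average_controllability(normalized_system_raw(matrix(0, 5, 5)))),
               rep(1, 5))
  # AC_k >= 1 under singular-value normalization
  w <- random_sym_graph(12, density = 0.5, seed = 9)
  ac <- average_controllability(normalize_adjacency(w, "singular_value"))
  expect_true(all(ac >= 1))
})

test_that("Lyapunov-solved Gramian trace matches the truncated-sum oracle", {
  for (seed in 1:10) {
    w <- random_sym_graph(10, density = 0.5, seed = 100 + seed)
    S <- normalize_adjacency(w, "singular_value")
    ac <- average_controllability(S)
    k <- (seed %% 10) + 1
    expect_equal(ac[[k]], sum(diag(gramian_truncated(S$A_norm, k))),
                 tolerance = 1e-8)
    W <- controllability_gramian(S, k)
    expect_equal(W, gramian_truncated(S$A_norm, k), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("modal controllability matches closed forms and the oracle", {
  # diagonal system: identity eigenvectors
  expect_equal(unname(modal_controllability(normalized_system_raw(diag(c(0.5, -0.2))))),
               c(0.75, 0.96), tolerance = 1e-12)
  # zero matrix: phi_k = 1 by eigenvector orthonormality
  expect_equal(unname(modal_controllability(normalized_system_raw(matrix(0, 4, 4)))),
               rep(1, 4))
  # independent eigendecomposition oracle on random symmetric systems
  for (seed in 1:5) {
    w <- random_sym_graph(6, density = 0.8, seed = 200 + seed)
    S <- normalize_adjacency(w, "singular_value")
    expect_equal(unname(modal_controllability(S)), modal_oracle(S$A_norm),
                 tolerance = 1e-10)
  }
  # complex modes unsupported
  expect_error(modal_controllability(normalized_system_raw(matrix(c(0, 1, 0, 0), 2))),
               "symmetric")
})

test_that("MC lies in [0, n] and mode weights in [0, 1] for stable systems", {
  for (seed in 1:10) {
    n <- sample(5:12, 1)
    w <- random_sym_graph(n, density = 0.5, seed = 300 + seed)
    S <- normalize_adjacency(w, sample(c("singular_value",
                                         "spectral_radius"), 1))
    mc <- modal_controllability(S)
    expect_true(all(mc >= 0 & mc <= n))
    lam <- eigen(S$A_norm, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(1 - lam^2 >= 0 & 1 - lam^2 <= 1))
  }
})

test_that("AC and MC are permutation-equivariant", {
  w <- random_sym_graph(8, density = 0.6, seed = 11)
  S <- normalize_adjacency(w, "singular_value")
  ac <- unname(average_controllability(S))
  mc <- unname(modal_controllability(S))
  set.seed(12)
  p <- sample(8)
  Sp <- normalize_adjacency(w[p, p], "singular_value")
  expect_equal(unname(average_controllability(Sp)), ac[p], tolerance = 1e-9)
  expect_equal(unname(modal_controllability(Sp)), mc[p], tolerance = 1e-9)
})

test_that("scalar AC increases strictly with |a| on [0, 1)", {
  a <- seq(0, 0.95, by = 0.05)
  ac <- sapply(a, function(x)
    average_controllability(normalized_system_raw(matrix(x, 1, 1))))
  expect_true(all(diff(ac) > 0))
})

test_that("Kalman rank classifies the worked examples", {
  # identity dynamics, single input: AB = B, rank 1
  r <- kalman_rank(normalized_system_raw(diag(2)), 1)
  expect_identical(r$rank, 1L)
  expect_false(r$full_rank)
  # shift pair: columns e2, e1 span the plane
  r <- kalman_rank(normalized_system_raw(matrix(c(0, 0, 1, 0), 2)), 2)
  expect_identical(r$rank, 2L)
  expect_true(r$full_rank)
  # B = I is always full rank
  w <- random_sym_graph(7, density = 0.4, seed = 13)
  r <- kalman_rank(normalize_adjacency(w), seq_len(7))
  expect_identical(r$rank, 7L)
  expect_true(r$full_rank)
  expect_error(kalman_rank(normalized_system_raw(diag(2)), integer(0)),
               "non-empty")
})

test_that("control_profile returns a tidy per-region table", {
  co <- tiny_cohort(n_subjects = 1, n_regions = 12, seed = 77)
  p <- control_profile(co$connectomes[[1]], proportion = 0.2)
  expect_s3_class(p, "control_profile")
  expect_identical(nrow(p), 12L)
  expect_identical(names(p),
                   c("subject_id", "region_name", "ac", "mc", "strength"))
  expect_true(all(p$ac >= 1))
  expect_true(all(p$mc >= 0 & p$mc <= 12))
  # strength column is computed on the thresholded matrix
  thr <- threshold_proportional(co$connectomes[[1]], 0.2)
  expect_equal(p$strength, unname(node_strength(thr)))
})
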
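# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive: brute-force sums and O(m^2)
# rankings that are easy to verify by eye, never the package's own path.

# Truncated-sum controllability Gramian: sum A^i B B' (A')^i until the
# Frobenius norm of the increment drops below tol.
gramian_truncated <- function(A, k, tol = 1e-14, max_iter = 100000) {
  n <- nrow(A)
  B <- matrix(0, n, 1)
  B[k, 1] <- 1
  term <- B %*% t(B)
  W <- term
  Ai <- diag(n)
  for (i in seq_len(max_iter)) {
    Ai <- A %*% Ai
    term <- Ai %*% B %*% t(B) %*% t(Ai)
    W <- W + term
    if (sqrt(sum(term^2)) < tol) return(W)
  }
  stop("truncated Gramian did not converge")
}

# Modal controllability recomputed from a separate (general, dgeev-based)
# eigendecomposition with explicit renormalization of the eigenvectors.
modal_oracle <- function(A) {
  e <- eigen(A, symmetric = FALSE)
  V <- Re(e$vectors)
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  lam <- Re(e$values)
  as.vector(V^2 %*% (1 - lam^2))
}

# Exhaustive proportional-threshold oracle: O(m^2) pairwise ranking with
# the stated tie rule (descending weight, ties by ascending (i, j)).
threshold_oracle <- function(w, proportion) {
  n <- nrow(w)
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    edges <- rbind(edges, c(i, j, w[i, j]))
  m <- nrow(edges)
  k <- floor(proportion * m + 0.5)
  beats <- function(a, b) {   # does edge a outrank edge b?
    if (a[3] != b[3]) return(a[3] > b[3])
    if (a[1] != b[1]) return(a[1] < b[1])
    a[2] < b[2]
  }
  rank_of <- sapply(seq_len(m), function(e) {
    1 + sum(sapply(seq_len(m)[-e], function(o)
      beats(edges[o, ], edges[e, ])))
  })
  out <- matrix(0, n, n)
  for (e in which(rank_of <= k))
    out[edges[e, 1], edges[e, 2]] <- out[edges[e, 2], edges[e, 1]] <- edges[e, 3]
  out
}

# Small random symmetric weighted graph with all-positive edge weights.
random_sym_graph <- function(n, density = 0.4, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  pick <- sample(ut, max(4, round(density * length(ut))))
  w[pick] <- runif(length(pick), 0.5, 5)
  w + t(w)
}

# Tiny cohort for pipeline-level tests (kept small for speed).
tiny_cohort <- function(n_subjects = 6, n_regions = 20, coupling = 0.5,
                        seed = 42) {
  generate_cohort(cohort_config(n_subjects = n_subjects,
                                n_regions = n_regions,
                                rgm_topology_coupling = coupling,
                                seed = seed))
}

# Rank-Gaussianize a vector (used to measure the coupling contract on the
# scale on which the generator enforces it).
rank_gauss <- function(x) qnorm((rank(x) - 0.5) / length(x))

expect_silent_fit <- function(expr) {
  suppressMessages(suppressWarnings(expr))
}
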
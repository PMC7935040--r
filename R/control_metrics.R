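#' Normalized linear system
#'
#' The control metrics assume discrete-time noise-free linear dynamics
#' `x(t+1) = A x(t) + B u(t)` whose state matrix must be Schur-stable
#' (spectral radius < 1) for the infinite-horizon controllability Gramian
#' `W_k = sum_{i>=0} A^i B B' (A')^i` to converge. Structural connectomes
#' are not stable as read, so the adjacency is scaled once, up front:
#'
#' * `"singular_value"` (default): divide by `1 + sigma_max(A)`, the
#'   convention of the network-controllability literature;
#' * `"spectral_radius"`: divide by `1 + rho(A)`;
#' * `"none"`: pass `A` through unchanged; the Gramian step then verifies
#'   stability itself and errors naming the offending radius.
#'
#' @param C [connectivity_matrix()] or numeric square matrix.
#' @param scheme normalization scheme (see above).
#' @return Object of class `normalized_system`: list with `A_norm`,
#'   `normalization_factor`, `scheme`, `subject_id`.
#' @examples
#' S <- normalize_adjacency(matrix(c(0, 1, 1, 0), 2))
#' S$normalization_factor  # 1 + sigma_max = 2
#' @export
normalize_adjacency <- function(C, scheme = c("singular_value",
                                              "spectral_radius", "none")) {
  scheme <- match.arg(scheme)
  A <- as_weights(C)
  if (nrow(A) != ncol(A)) stop_ctrl("adjacency must be square")
  if (any(!is.finite(A))) stop_ctrl("adjacency has non-finite entries")
  factor <- switch(scheme,
    singular_value = 1 + max(svd(A, nu = 0, nv = 0)$d),
    spectral_radius = 1 + max(Mod(eigen(A, only.values = TRUE)$values)),
    none = 1)
  subject_id <- if (inherits(C, "connectivity_matrix")) C$subject_id else NA_character_
  structure(list(A_norm = A / factor,
                 normalization_factor = factor,
                 scheme = scheme,
                 subject_id = subject_id),
            class = "normalized_system")
}

#' @export
print.normalized_system <- function(x, ...) {
  cat("<normalized_system> n = ", nrow(x$A_norm),
      ", scheme = ", x$scheme,
      ", factor = ", format(x$normalization_factor),
      ", spectral radius = ", format(spectral_radius(x$A_norm)), "\n",
      sep = "")
  invisible(x)
}

as_system <- function(S) {
  if (inherits(S, "normalized_system")) return(S)
  normalize_adjacency(S, scheme = "none")
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

is_symmetric <- function(A, tol = 1e-10) {
  max(abs(A - t(A))) <= tol * max(abs(A), 1e-300)
}

check_stable <- function(A) {
  rho <- spectral_radius(A)
  if (rho >= 1)
    stop_ctrl("Gramian sum diverges: spectral radius ", format(rho),
              " >= 1; normalize the adjacency first")
  rho
}

# Eigendecomposition shared by the Gramian, AC and MC paths for symmetric A.
sym_eigen <- function(A) {
  if (!is_symmetric(A))
    stop_ctrl("matrix must be symmetric (undirected connectome)")
  eigen((A + t(A)) / 2, symmetric = TRUE)
}

#' Controllability Gramian for a single control node
#'
#' Solves the discrete-time stationary Lyapunov equation
#' `W = A W A' + B B'` with `B = e_k` (the indicator of the control node),
#' which is the closed form of the infinite sum `sum_i A^i B B' (A')^i`.
#' For symmetric `A` (the only case arising from undirected connectomes)
#' the solve is exact in the eigenbasis:
#' `W = V ( (V'BB'V) / (1 - lambda_i lambda_j) ) V'`.
#' A dense Kronecker solve backs the non-symmetric case for small systems.
#'
#' @param S [normalize_adjacency()] result (or matrix, taken as scheme
#'   `"none"`).
#' @param control_node 1-based node index k.
#' @return n x n symmetric positive-semidefinite Gramian.
#' @examples
#' S <- normalized_system_raw(matrix(0.5, 1, 1))
#' controllability_gramian(S, 1)  # 1 / (1 - 0.25) = 4/3
#' @export
controllability_gramian <- function(S, control_node) {
  S <- as_system(S)
  A <- S$A_norm
  n <- nrow(A)
  k <- as.integer(control_node)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n)
    stop_ctrl("control_node must be a single index in 1..", n)
  check_stable(A)
  if (is_symmetric(A)) {
    e <- sym_eigen(A)
    lam <- e$values
    V <- e$vectors
    bk <- V[k, ]                     # V' e_k
    M <- outer(bk, bk) / (1 - outer(lam, lam))
    W <- V %*% M %*% t(V)
  } else {
    if (n > 80)
      stop_ctrl("dense Lyapunov solve limited to n <= 80 for ",
                "non-symmetric systems")
    BBt <- matrix(0, n, n)
    BBt[k, k] <- 1
    W <- matrix(solve(diag(n * n) - kronecker(A, A), as.vector(BBt)), n, n)
  }
  (W + t(W)) / 2
}

#' Average controllability
#'
#' `AC_k = trace(W_k)`: the trace of the single-node controllability
#' Gramian, a proxy for the average ease (inverse energy) with which node k
#' can steer the network to all possible states. For symmetric `A_norm` with
#' orthonormal eigenvectors `v` and eigenvalues `xi`, the Gramian trace is
#' `AC_k = sum_j v_kj^2 / (1 - xi_j^2)`, which the implementation uses; this
#' is algebraically identical to tracing the Lyapunov solution, not an
#' approximation. Under singular-value normalization every `AC_k >= 1` (the
#' i = 0 term of the sum alone contributes 1).
#'
#' @param S [normalize_adjacency()] result or matrix.
#' @return Numeric vector of length n, one AC value per node.
#' @export
average_controllability <- function(S) {
  S <- as_system(S)
  A <- S$A_norm
  check_stable(A)
  if (is_symmetric(A)) {
    e <- sym_eigen(A)
    ac <- as.vector(e$vectors^2 %*% (1 / (1 - e$values^2)))
  } else {
    ac <- vapply(seq_len(nrow(A)),
                 function(k) sum(diag(controllability_gramian(S, k))),
                 numeric(1))
  }
  names(ac) <- rownames(A)
  ac
}

#' Modal controllability
#'
#' `phi_k = sum_j (1 - xi_j^2) v_kj^2`, with `xi_j` the eigenvalues and
#' `v_.j` the orthonormal eigenvectors of the (symmetric) normalized state
#' matrix: a scaled measure of node k's ability to excite all dynamical
#' modes, dominated by the fast-decaying, hard-to-reach ones. Requires a
#' symmetric matrix (complex modes are unsupported); sign flips of the
#' eigenvectors are irrelevant since only `v_kj^2` enters. For spectral
#' radius <= 1 every mode weight `1 - xi_j^2` lies in [0, 1], so
#' `phi_k` lies in [0, n].
#'
#' @param S [normalize_adjacency()] result or matrix.
#' @return Numeric vector of length n, one MC value per node.
#' @export
modal_controllability <- function(S) {
  S <- as_system(S)
  A <- S$A_norm
  e <- sym_eigen(A)
  mc <- as.vector(e$vectors^2 %*% (1 - e$values^2))
  names(mc) <- rownames(A)
  mc
}

#' Kalman rank test
#'
#' Numerical rank of the controllability matrix
#' `[B, AB, ..., A^(n-1) B]` with `B` the indicator columns of
#' `control_nodes`; the system is fully state controllable iff this matrix
#' has rank n. Rank is the count of singular values above
#' `max(dim) * eps * sigma_max`, a documented tolerance because Kalman
#' matrices are notoriously ill-conditioned.
#'
#' @param S [normalize_adjacency()] result or matrix (any scheme; stability
#'   is not required for the rank test).
#' @param control_nodes integer vector of 1-based control node indices.
#' @return List with `rank` (integer) and `full_rank` (logical).
#' @examples
#' kalman_rank(matrix(c(0, 0, 1, 0), 2), 2)$full_rank  # TRUE
#' @export
kalman_rank <- function(S, control_nodes) {
  S <- as_system(S)
  A <- S$A_norm
  n <- nrow(A)
  ks <- unique(as.integer(control_nodes))
  if (length(ks) == 0L || anyNA(ks) || any(ks < 1L | ks > n))
    stop_ctrl("control_nodes must be a non-empty set of indices in 1..", n)
  B <- diag(n)[, ks, drop = FALSE]
  blocks <- vector("list", n)
  blocks[[1]] <- B
  for (i in seq_len(n - 1L)) blocks[[i + 1L]] <- A %*% blocks[[i]]
  K <- do.call(cbind, blocks)
  d <- svd(K, nu = 0, nv = 0)$d
  tol <- max(dim(K)) * .Machine$double.eps * max(d, 0)
  r <- sum(d > tol)
  list(rank = as.integer(r), full_rank = r == n)
}

#' Construct a normalized system from an already-scaled matrix
#'
#' Convenience constructor for tests and worked examples where `A_norm` is
#' given directly (e.g. `diag(c(0.5, -0.2))`) rather than derived from a
#' connectome.
#'
#' @param A_norm numeric square matrix, assumed already scaled.
#' @param scheme label recorded on the object.
#' @return A `normalized_system`.
#' @export
normalized_system_raw <- function(A_norm, scheme = "none") {
  A_norm <- as.matrix(A_norm)
  if (nrow(A_norm) != ncol(A_norm)) stop_ctrl("A_norm must be square")
  if (any(!is.finite(A_norm))) stop_ctrl("A_norm has non-finite entries")
  structure(list(A_norm = A_norm, normalization_factor = 1,
                 scheme = scheme, subject_id = NA_character_),
            class = "normalized_system")
}

#' Per-node control profile for one subject
#'
#' Thresholds (optionally), normalizes, and computes AC, MC and strength
#' for one subject's connectome, returning the tidy per-region table the
#' study assembly consumes. Strength is computed on the thresholded,
#' unnormalized matrix (normalization rescales the dynamics, not the
#' connectivity summary); AC and MC are computed on the same thresholded,
#' normalized matrix.
#'
#' @param C [connectivity_matrix()].
#' @param proportion proportional-threshold fraction in (0, 1]; `NULL`
#'   skips thresholding (matrix assumed already thresholded).
#' @param scheme normalization scheme, see [normalize_adjacency()].
#' @return `control_profile`: data.frame with columns `subject_id`,
#'   `region_name`, `ac`, `mc`, `strength`.
#' @export
control_profile <- function(C, proportion = 0.10,
                            scheme = c("singular_value", "spectral_radius",
                                       "none")) {
  scheme <- match.arg(scheme)
  if (!inherits(C, "connectivity_matrix"))
    stop_ctrl("control_profile expects a connectivity_matrix")
  if (!is.null(proportion)) C <- threshold_proportional(C, proportion)
  S <- normalize_adjacency(C, scheme)
  out <- data.frame(subject_id = C$subject_id,
                    region_name = C$atlas$region_name,
                    ac = as.vector(average_controllability(S)),
                    mc = as.vector(modal_controllability(S)),
                    strength = as.vector(node_strength(C)),
                    stringsAsFactors = FALSE)
  class(out) <- c("control_profile", "data.frame")
  out
}

#' Write control profiles as tidy TSV
#'
#' @param profiles a `control_profile` or list of them.
#' @param path output path.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "data.frame")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
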
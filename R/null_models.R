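#' Degree-preserving randomization of a weighted connectome
#'
#' Maslov-Sneppen double-edge swaps on the undirected weighted graph: each
#' attempted swap draws two edges (a,b) and (c,d), proposes rewiring to
#' (a,d) and (c,b) (endpoints shuffled at random), and accepts unless the
#' move would create a self-loop or a multi-edge. Weights travel with their
#' edge, so the move conserves the *binary* degree sequence, the edge count
#' and the multiset of edge weights exactly. Node strength (weighted
#' degree) is deliberately NOT preserved — that is the point of the null:
#' it destroys the alignment between weight placement and topology while
#' keeping the degree distribution.
#'
#' `swaps_per_edge * |E|` swaps are attempted; if none succeeds (degenerate
#' graphs) a warning reports the success count.
#'
#' @param C [connectivity_matrix()] or numeric matrix.
#' @param swaps_per_edge attempted swaps per edge (default 10, the standard
#'   mixing heuristic).
#' @param seed integer seed; the output is a pure function of (input, seed).
#' @return Same type as `C`, rewired.
#' @export
rewire_preserving_degree <- function(C, swaps_per_edge = 10, seed) {
  if (missing(seed)) stop_ctrl("rewire_preserving_degree requires a seed")
  if (swaps_per_edge < 1) stop_ctrl("swaps_per_edge must be >= 1")
  w <- as_weights(C)
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  ne <- nrow(ut)
  if (ne < 4L)
    stop_ctrl("graph has ", ne, " edges; need >= 4 for degree-preserving ",
              "rewiring")
  ei <- ut[, 1]; ej <- ut[, 2]
  ew <- w[ut]
  adj <- w > 0
  n_attempt <- as.integer(round(swaps_per_edge * ne))
  successes <- 0L
  with_seed(seed, {
    for (t in seq_len(n_attempt)) {
      pick <- sample.int(ne, 2L)
      e1 <- pick[1]; e2 <- pick[2]
      a <- ei[e1]; b <- ej[e1]
      c <- ei[e2]; d <- ej[e2]
      if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      # proposed new edges: (a,d) and (c,b)
      if (a == d || c == b) next
      if (adj[a, d] || adj[c, b]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c, d] <- adj[d, c] <- FALSE
      adj[a, d] <- adj[d, a] <- TRUE
      adj[c, b] <- adj[b, c] <- TRUE
      ei[e1] <- min(a, d); ej[e1] <- max(a, d)
      ei[e2] <- min(c, b); ej[e2] <- max(c, b)
      successes <- successes + 1L
    }
  })
  if (successes == 0L)
    warn_ctrl("no legal swap found in ", n_attempt,
              " attempts; graph returned unchanged (successes = 0)")
  out <- matrix(0, n, n, dimnames = dimnames(w))
  out[cbind(ei, ej)] <- ew
  out <- out + t(out)
  if (inherits(C, "connectivity_matrix")) {
    C$weights <- out
    C
  } else out
}

#' Null-network test of the gray-matter coefficient
#'
#' Asks whether the regression weight of regional gray matter (rGM) on a
#' controllability outcome depends on the actual placement of connections,
#' or would arise for any network with the same degree distribution. For
#' each of `n_replicates` replicates, every subject's thresholded
#' connectome is rewired with [rewire_preserving_degree()], AC/MC/strength
#' are recomputed, the mixed model is refitted, and the rGM coefficient is
#' recorded. The one-sided empirical p-value
#' `p = (1 + #\{null beta >= original beta\}) / (R + 1)` follows the
#' direction reported for real connectomes (original coefficient larger
#' than in randomized networks); `alternative = "two.sided"` doubles the
#' smaller tail.
#'
#' Replicates whose fit fails with an error are excluded and counted; more
#' than 10% failures aborts.
#'
#' @param connectomes list of [connectivity_matrix()], one per subject
#'   (un-thresholded; thresholding is applied here, before rewiring).
#' @param volumetrics list of [subject_volumetrics()].
#' @param spec [model_spec()] to refit on each replicate; default model 1
#'   with response `ac`.
#' @param coef_term canonical name of the tracked coefficient
#'   (default `"rgm"`).
#' @param n_replicates number of randomized replicates R (the reference
#'   analysis used 1,000; tests use fewer).
#' @param seed master seed; per-(replicate, subject) substreams are derived
#'   from it, so results are independent of execution order.
#' @param proportion,scheme,swaps_per_edge pipeline settings, as in
#'   [control_profile()] and [rewire_preserving_degree()].
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param scale_within passed to [center_and_scale()].
#' @return Object of class `null_distribution`: list with `original_beta`,
#'   `null_betas`, `n_replicates`, `n_failures`, `p_value`, `alternative`,
#'   `seed`.
#' @export
null_beta_test <- function(connectomes, volumetrics,
                           spec = model_spec_one("ac"),
                           coef_term = "rgm",
                           n_replicates = 1000, seed,
                           proportion = 0.10,
                           scheme = "singular_value",
                           swaps_per_edge = 10,
                           alternative = c("greater", "two.sided"),
                           scale_within = FALSE) {
  alternative <- match.arg(alternative)
  if (missing(seed)) stop_ctrl("null_beta_test requires a seed")
  if (n_replicates < 1) stop_ctrl("n_replicates must be >= 1 (empty null)")
  thresholded <- lapply(connectomes, threshold_proportional,
                        proportion = proportion)
  fit_beta <- function(mats) {
    profiles <- lapply(mats, control_profile, proportion = NULL,
                       scheme = scheme)
    tab <- assemble(profiles, volumetrics)
    tab <- center_and_scale(tab, scale_within = scale_within)
    fit <- fit_lme(tab, spec, method = "ML")
    co <- fit$coefficients
    term <- canonical_to_column(coef_term)
    if (!term %in% co$term)
      stop_ctrl("coefficient ", term, " absent from fitted model")
    co$beta[co$term == term]
  }
  original_beta <- fit_beta(thresholded)
  null_betas <- rep(NA_real_, n_replicates)
  failures <- 0L
  for (r in seq_len(n_replicates)) {
    rew <- lapply(seq_along(thresholded), function(s) {
      rewire_preserving_degree(
        thresholded[[s]], swaps_per_edge = swaps_per_edge,
        seed = seed_stream(seed, "nullrep", r, s))
    })
    names(rew) <- names(thresholded)
    b <- tryCatch(fit_beta(rew), error = function(e) NA_real_)
    if (is.na(b)) failures <- failures + 1L else null_betas[r] <- b
    if (failures > 0.1 * n_replicates)
      stop_ctrl("more than 10% of null replicates failed to fit (",
                failures, "/", n_replicates, ")")
  }
  nb <- null_betas[!is.na(null_betas)]
  R <- length(nb)
  p_greater <- (1 + sum(nb >= original_beta)) / (R + 1)
  p_less <- (1 + sum(nb <= original_beta)) / (R + 1)
  p <- switch(alternative,
              greater = p_greater,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  structure(list(original_beta = original_beta,
                 null_betas = nb,
                 n_replicates = as.integer(n_replicates),
                 n_failures = failures,
                 p_value = p,
                 alternative = alternative,
                 seed = as.integer(seed)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> original beta = ", format(x$original_beta),
      ", ", length(x$null_betas), " null replicates (",
      x$n_failures, " failed), p (", x$alternative, ") = ",
      format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Write a null distribution as TSV plus JSON summary
#'
#' @param nd a `null_distribution`.
#' @param path_tsv per-replicate beta table path.
#' @param path_json summary path.
#' @export
write_null_distribution <- function(nd, path_tsv, path_json) {
  utils::write.table(
    data.frame(replicate = seq_along(nd$null_betas), beta = nd$null_betas),
    path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(original_beta = nd$original_beta, p_value = nd$p_value,
         n_replicates = nd$n_replicates, n_failures = nd$n_failures,
         alternative = nd$alternative, seed = nd$seed),
    path_json, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
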
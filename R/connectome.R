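#' Connectivity matrix
#'
#' Wraps one subject's weighted structural connectome: a square, symmetric,
#' non-negative matrix of streamline counts (or derived weights) with zero
#' diagonal, bound to a [region_atlas()]. This matrix is the state matrix of
#' the linear dynamics the controllability metrics are computed on.
#'
#' Validation rules:
#' * entries must be finite and non-negative;
#' * asymmetry up to `1e-9 * max(w)` is repaired as `(W + t(W))/2`, anything
#'   larger is an error (directed connectomes are out of scope);
#' * a nonzero diagonal is forced to zero with a warning.
#'
#' @param weights numeric n x n matrix.
#' @param atlas a [region_atlas()] with n regions; a default anonymous atlas
#'   is built when omitted.
#' @param subject_id subject label carried through the pipeline.
#' @return Object of class `connectivity_matrix`: list with elements
#'   `weights`, `atlas`, `subject_id`.
#' @export
connectivity_matrix <- function(weights, atlas = NULL, subject_id = "subject") {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop_ctrl("connectivity matrix must be square, got ",
              nrow(weights), "x", ncol(weights))
  if (!is.numeric(weights) || any(!is.finite(weights)))
    stop_ctrl("connectivity matrix has non-finite or non-numeric entries")
  if (any(weights < 0))
    stop_ctrl("connectivity matrix has negative entries")
  n <- nrow(weights)
  if (is.null(atlas)) atlas <- region_atlas(sprintf("region_%03d", seq_len(n)))
  if (nrow(atlas) != n)
    stop_ctrl("matrix dimension ", n, " does not match atlas size ",
              nrow(atlas))
  asym <- max(abs(weights - t(weights)))
  tol <- 1e-9 * max(weights, 1e-300)
  if (asym > tol)
    stop_ctrl("matrix asymmetry ", format(asym),
              " exceeds tolerance ", format(tol),
              "; directed connectomes are unsupported")
  if (asym > 0) weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    warn_ctrl("nonzero diagonal set to zero for subject ", subject_id)
    diag(weights) <- 0
  }
  dimnames(weights) <- list(atlas$region_name, atlas$region_name)
  structure(list(weights = weights, atlas = atlas,
                 subject_id = as.character(subject_id)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  w <- x$weights
  cat("<connectivity_matrix> subject ", x$subject_id, ": ",
      nrow(w), " regions, ", sum(w[upper.tri(w)] > 0), " edges, ",
      "max weight ", format(max(w)), "\n", sep = "")
  invisible(x)
}

# Accept either a connectivity_matrix or a bare numeric matrix.
as_weights <- function(C) {
  if (inherits(C, "connectivity_matrix")) C$weights else as.matrix(C)
}

#' Read a connectome matrix from delimited text
#'
#' Accepts comma- or tab-delimited n x n numeric matrices, with an optional
#' header row and/or leading column of region names (both dialects circulate
#' for tractography-derived matrices). The result is validated, symmetrized
#' within tolerance and bound to `atlas`.
#'
#' @param path file path.
#' @param atlas a [region_atlas()]; the matrix must match its size.
#' @param subject_id subject label; defaults to the file stem.
#' @return A [connectivity_matrix()].
#' @export
read_connectome <- function(path, atlas,
                            subject_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop_ctrl("connectome file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(
    fields[fields != ""][-1])))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.numeric(df[[1]])) df <- df[, -1, drop = FALSE]  # row-name column
  w <- suppressWarnings(apply(as.matrix(df), c(1, 2), as.numeric))
  if (anyNA(w)) stop_ctrl("non-numeric entries in ", path)
  connectivity_matrix(w, atlas = atlas, subject_id = subject_id)
}

#' Write a connectome matrix as TSV
#'
#' @param C a [connectivity_matrix()].
#' @param path output path.
#' @export
write_connectome <- function(C, path) {
  w <- as_weights(C)
  utils::write.table(w, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Proportional threshold of a weighted connectome
#'
#' Retains the strongest `proportion` of the n(n-1)/2 possible undirected
#' edges and zeroes the rest, the standard robustness step before control
#' metrics (default in the pipeline: 0.10, i.e. keep the top 10% of
#' connections). The retained count is `round_half_up(proportion * m)` over
#' the m possible upper-triangle edges; ties at the cutoff are broken by
#' ascending (row, column) index so the output is deterministic and the edge
#' count exact. Surviving weights are unchanged.
#'
#' @param C [connectivity_matrix()] or numeric matrix.
#' @param proportion fraction of possible edges to keep, in (0, 1].
#' @return Same type as `C`, thresholded.
#' @examples
#' w <- matrix(0, 4, 4)
#' w[upper.tri(w)] <- 1:6
#' w <- w + t(w)
#' threshold_proportional(w, 0.5)  # keeps the 3 strongest edges
#' @export
threshold_proportional <- function(C, proportion) {
  if (!is.numeric(proportion) || length(proportion) != 1L ||
      !is.finite(proportion) || proportion <= 0 || proportion > 1)
    stop_ctrl("proportion must be a single number in (0, 1]")
  w <- as_weights(C)
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  m <- nrow(ut)
  k <- floor(proportion * m + 0.5)  # round half up
  wv <- w[upper.tri(w)]
  # rank by decreasing weight, ties by ascending (row, col) index
  ord <- order(-wv, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  out <- matrix(0, n, n, dimnames = dimnames(w))
  idx <- cbind(ut[keep, 1], ut[keep, 2])
  out[idx] <- wv[keep]
  out <- out + t(out)
  if (inherits(C, "connectivity_matrix")) {
    C$weights <- out
    C
  } else out
}

#' Node strength (weighted degree)
#'
#' Row sums of the weighted adjacency matrix. In the connectome literature
#' this row sum of streamline counts is commonly called "nodal degree"; the
#' statistical models in this package use it under that name.
#'
#' @param C [connectivity_matrix()] or numeric matrix.
#' @return Named numeric vector of length n.
#' @export
node_strength <- function(C) {
  rowSums(as_weights(C))
}
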
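#' Construct a connectome from strength and length matrices
#'
#' A connectome pairs a symmetric, zero-diagonal strength matrix `W`
#' (dimensionless connection strengths, `w_ij >= 0`, with `w_ij = 0` meaning
#' the edge is absent) with a symmetric mean fiber-length matrix `L` in mm
#' (`l_ij > 0` wherever `w_ij > 0`). Lengths are retained only where the
#' corresponding strength is positive.
#'
#' @param W N x N non-negative strength matrix.
#' @param L N x N fiber-length matrix (mm).
#' @param region_ids Integer region labels in matrix order; defaults to
#'   `1:N`.
#' @return An object of class `neteff_connectome`.
#' @seealso [build_connectome()] for the full raw-counts-to-connectome path,
#'   [validate_connectome()] for invariant checking.
#' @export
connectome <- function(W, L, region_ids = NULL) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    abort("W must be a square matrix", class = "neteff_error_connectome")
  }
  if (!is.matrix(L) || !all(dim(L) == dim(W))) {
    abort(sprintf("L (%dx%d) must match W (%dx%d)",
                  nrow(L), ncol(L), nrow(W), ncol(W)),
          class = "neteff_error_connectome")
  }
  if (any(W < 0)) {
    abort("negative strengths are not allowed", class = "neteff_error_connectome")
  }
  n <- nrow(W)
  if (is.null(region_ids)) region_ids <- seq_len(n)
  diag(W) <- 0
  L[W == 0] <- 0
  if (any(W > 0 & L <= 0)) {
    bad <- which(W > 0 & L <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("edge (%d,%d) has positive strength but no length",
                  region_ids[bad[1]], region_ids[bad[2]]),
          class = "neteff_error_connectome")
  }
  dimnames(W) <- dimnames(L) <- list(region_ids, region_ids)
  structure(list(n = n, W = W, L = L, region_ids = as.integer(region_ids)),
            class = "neteff_connectome")
}

#' @export
print.neteff_connectome <- function(x, ...) {
  ne <- sum(x$W[upper.tri(x$W)] > 0)
  cat(sprintf("<neteff_connectome> %d regions, %d edges (density %.2f), max strength %.4g\n",
              x$n, ne, ne / (x$n * (x$n - 1) / 2), max(x$W)))
  invisible(x)
}

#' Size-normalized connection strength
#'
#' Converts a tract-count matrix into a strength index by dividing each
#' count by the mean size of the two regions it connects:
#' `strength_ij = counts_ij / ((size_i + size_j) / 2)`. The diagonal is
#' forced to zero (self-connections are discarded).
#'
#' @param counts N x N non-negative tract-count matrix.
#' @param region_sizes Length-N vector of positive region sizes.
#' @return N x N strength matrix.
#' @examples
#' compile_strength(matrix(c(0, 100, 100, 0), 2), c(20, 30))[1, 2] # 4
#' @export
compile_strength <- function(counts, region_sizes) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    abort("counts must be a square matrix", class = "neteff_error_connectome")
  }
  if (length(region_sizes) != nrow(counts)) {
    abort(sprintf("region_sizes has length %d but counts is %dx%d",
                  length(region_sizes), nrow(counts), ncol(counts)),
          class = "neteff_error_connectome")
  }
  if (any(!is.finite(region_sizes)) || any(region_sizes <= 0)) {
    bad <- which(!is.finite(region_sizes) | region_sizes <= 0)
    abort(paste0("non-positive size for region(s) at position(s): ",
                 paste(bad, collapse = ", ")),
          class = "neteff_error_connectome")
  }
  if (any(counts < 0)) {
    abort("negative counts are not allowed", class = "neteff_error_connectome")
  }
  mean_size <- outer(region_sizes, region_sizes, function(a, b) (a + b) / 2)
  strength <- counts / mean_size
  diag(strength) <- 0
  strength
}

#' Symmetrize a square matrix by the arithmetic mean
#'
#' Tractography seeded from both ends of a tract yields (mildly) asymmetric
#' count matrices; the undirected matrix is taken as the elementwise mean of
#' the two directions.
#'
#' @param M A square matrix.
#' @param mode Reduction mode; only `"mean"` is defined.
#' @return An exactly symmetric matrix `(M + t(M)) / 2`.
#' @export
symmetrize <- function(M, mode = "mean") {
  mode <- match.arg(mode)
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    abort("M must be a square matrix", class = "neteff_error_connectome")
  }
  (M + t(M)) / 2
}

#' Count-weighted symmetrization of a length matrix
#'
#' Mean fiber lengths from the two seeding directions are combined with
#' weights proportional to the directional tract counts, so the direction
#' carrying more streamlines dominates; where only one direction has tracts
#' its length is used as-is.
#'
#' @param L Square matrix of directional mean lengths (mm).
#' @param counts Square matrix of directional tract counts.
#' @return Symmetric length matrix.
#' @export
symmetrize_lengths <- function(L, counts) {
  if (!is.matrix(L) || nrow(L) != ncol(L) || !all(dim(L) == dim(counts))) {
    abort("L and counts must be square matrices of equal size",
          class = "neteff_error_connectome")
  }
  num <- counts * L + t(counts * L)
  den <- counts + t(counts)
  out <- ifelse(den > 0, num / den, 0)
  out
}

#' Build a connectome from raw directional matrices
#'
#' Runs the full compilation: counts are symmetrized by the arithmetic mean,
#' lengths by the count-weighted mean, counts are converted to the
#' size-normalized strength index, and the pair is validated into a
#' [connectome()].
#'
#' @param counts N x N (possibly asymmetric) tract-count matrix.
#' @param lengths N x N mean fiber-length matrix (mm).
#' @param atlas A [region_atlas()] supplying region sizes and ids.
#' @return A `neteff_connectome`.
#' @export
build_connectome <- function(counts, lengths, atlas) {
  sym_counts <- symmetrize(counts)
  sym_lengths <- symmetrize_lengths(lengths, counts)
  W <- compile_strength(sym_counts, atlas$size)
  connectome(W, sym_lengths, region_ids = atlas$region_id)
}

#' Rescale connection strengths to a unit maximum
#'
#' Divides all strengths by the subject's maximum strength so that
#' `w in [0, 1]`. This removes the arbitrary scale of tract counts and bounds
#' the cube-root weight term of weighted local efficiency; it is applied
#' per subject before any efficiency computation in the pipeline.
#'
#' @param conn A `neteff_connectome`.
#' @return The connectome with `max(W) == 1` (unchanged if empty).
#' @export
rescale_weights <- function(conn) {
  stopifnot(inherits(conn, "neteff_connectome"))
  mx <- max(conn$W)
  if (mx > 0) conn$W <- conn$W / mx
  conn
}

#' Check connectome invariants
#'
#' Reports (rather than errors on) violations of the connectome contract:
#' asymmetry of `W` or `L` beyond `1e-10`, negative strengths, positive
#' strength with missing length, and nonzero diagonal (self-loop).
#'
#' @param conn A `neteff_connectome` (or a bare list with `W` and `L`).
#' @return A tibble with columns `violation`, `i`, `j`, `detail`; zero rows
#'   if and only if the connectome is valid.
#' @export
validate_connectome <- function(conn) {
  W <- conn$W
  L <- conn$L
  ids <- conn$region_ids %||% seq_len(nrow(W))
  rows <- list()
  add <- function(violation, i, j, detail) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      violation = violation, i = ids[i], j = ids[j], detail = detail)
  }
  asym_w <- abs(W - t(W))
  if (max(asym_w) > 1e-10) {
    idx <- which(asym_w == max(asym_w), arr.ind = TRUE)[1, ]
    add("asymmetric_strength", idx[1], idx[2],
        sprintf("max |W - t(W)| = %.3g", max(asym_w)))
  }
  asym_l <- abs(L - t(L))
  if (max(asym_l) > 1e-10) {
    idx <- which(asym_l == max(asym_l), arr.ind = TRUE)[1, ]
    add("asymmetric_length", idx[1], idx[2],
        sprintf("max |L - t(L)| = %.3g", max(asym_l)))
  }
  if (any(W < 0)) {
    idx <- which(W < 0, arr.ind = TRUE)[1, ]
    add("negative_strength", idx[1], idx[2], sprintf("w = %.3g", W[idx[1], idx[2]]))
  }
  miss <- W > 0 & L <= 0
  if (any(miss)) {
    idx <- which(miss, arr.ind = TRUE)[1, ]
    add("missing_length", idx[1], idx[2],
        sprintf("w = %.3g but l = %.3g", W[idx[1], idx[2]], L[idx[1], idx[2]]))
  }
  if (any(diag(W) != 0)) {
    i <- which(diag(W) != 0)[1]
    add("self_loop", i, i, sprintf("diagonal w = %.3g", diag(W)[i]))
  }
  if (length(rows) == 0) {
    tibble::tibble(violation = character(), i = integer(), j = integer(),
                   detail = character())
  } else {
    dplyr::bind_rows(rows)
  }
}

#' Tidy a connectome into an edge list
#'
#' @param x A `neteff_connectome`.
#' @param ... Unused.
#' @return A tibble with one row per undirected edge: `from`, `to`,
#'   `strength`, `length`.
#' @export
tidy.neteff_connectome <- function(x, ...) {
  ut <- upper.tri(x$W)
  keep <- ut & x$W > 0
  idx <- which(keep, arr.ind = TRUE)
  tibble::tibble(
    from = x$region_ids[idx[, 1]],
    to = x$region_ids[idx[, 2]],
    strength = x$W[keep],
    length = x$L[keep]
  ) |> dplyr::arrange(.data$from, .data$to)
}

#' @export
glance.neteff_connectome <- function(x, ...) {
  ne <- sum(x$W[upper.tri(x$W)] > 0)
  tibble::tibble(
    n_regions = x$n,
    n_edges = ne,
    density = ne / (x$n * (x$n - 1) / 2),
    max_strength = max(x$W),
    min_length = if (ne > 0) min(x$L[x$W > 0]) else NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
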
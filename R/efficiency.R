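#' Weighted edge lengths
#'
#' The weighted travel distance along an edge is its fiber length divided by
#' its connection strength, `l_ij / w_ij`, so strong connections shorten the
#' effective distance. Absent edges (`w_ij = 0`) get length `Inf`. Strengths
#' are expected to be rescaled to a unit maximum (see [rescale_weights()])
#' before path computations so the edge lengths are bounded below by the
#' physical lengths.
#'
#' @param conn A `neteff_connectome`.
#' @return N x N symmetric matrix of edge lengths with `Inf` off-edges.
#' @export
weighted_edge_lengths <- function(conn) {
  stopifnot(inherits(conn, "neteff_connectome"))
  if (any(conn$W > 0 & conn$L <= 0)) {
    idx <- which(conn$W > 0 & conn$L <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("edge (%d,%d) has positive strength but non-positive length",
                  conn$region_ids[idx[1]], conn$region_ids[idx[2]]),
          class = "neteff_error_efficiency")
  }
  E <- ifelse(conn$W > 0, conn$L / conn$W, Inf)
  diag(E) <- Inf
  E
}

edge_length_matrix <- function(conn, weighted) {
  if (weighted) {
    weighted_edge_lengths(conn)
  } else {
    E <- ifelse(conn$W > 0, conn$L, Inf)
    diag(E) <- Inf
    E
  }
}

#' All-pairs shortest physical-path distances
#'
#' The distance between two regions is the smallest sum of edge lengths over
#' all paths connecting them (the travel distance, not the hop count nor the
#' Euclidean distance). Computed exactly for non-negative edge lengths;
#' unreachable pairs get `Inf` and the diagonal is zero.
#'
#' @param edge_lengths N x N matrix of non-negative edge lengths; `Inf`
#'   marks an absent edge.
#' @return N x N symmetric `DistanceMatrix`.
#' @export
shortest_path_distances <- function(edge_lengths) {
  if (!is.matrix(edge_lengths) || nrow(edge_lengths) != ncol(edge_lengths)) {
    abort("edge_lengths must be a square matrix", class = "neteff_error_efficiency")
  }
  if (any(edge_lengths < 0)) {
    abort("negative edge lengths are not allowed", class = "neteff_error_efficiency")
  }
  D <- fw_cpp(edge_lengths)
  dimnames(D) <- dimnames(edge_lengths)
  D
}

#' Raw nodal global efficiency
#'
#' For node i, the mean inverse shortest-path distance to all other nodes:
#' `E_i = (1/(N-1)) * sum_{j != i} 1 / d_ij`, with `1/Inf := 0` so
#' unreachable partners contribute nothing. With `weighted = TRUE` the
#' distances are weighted travel distances (edge lengths `l/w`); otherwise
#' physical fiber lengths.
#'
#' @param conn A `neteff_connectome` with at least 2 nodes.
#' @param weighted Use connection strengths in the distance (default `TRUE`).
#' @return Named numeric vector of raw (unnormalized) efficiencies.
#' @export
nodal_global_efficiency <- function(conn, weighted = TRUE) {
  stopifnot(inherits(conn, "neteff_connectome"))
  if (conn$n < 2) {
    abort("nodal global efficiency requires at least 2 nodes",
          class = "neteff_error_efficiency")
  }
  D <- shortest_path_distances(edge_length_matrix(conn, weighted))
  inv <- ifelse(is.finite(D) & D > 0, 1 / D, 0)
  diag(inv) <- 0
  setNames(rowSums(inv) / (conn$n - 1), conn$region_ids)
}

#' Raw nodal local efficiency
#'
#' For node i, efficiency is computed within the subgraph `G_i` of its
#' neighbors (`j` is a neighbor iff `w_ij > 0`), with shortest paths
#' restricted to edges among the neighbors. Unweighted:
#' `(1/(N_Gi (N_Gi - 1))) * sum_{j != k in G_i} 1 / d_jk`. Weighted, each
#' ordered-pair term is `((d^w_jk)^{-1} w_ij w_ik)^{1/3}`. A node with fewer
#' than 2 neighbors scores 0.
#'
#' @inheritParams nodal_global_efficiency
#' @return Named numeric vector of raw local efficiencies.
#' @export
nodal_local_efficiency <- function(conn, weighted = TRUE) {
  stopifnot(inherits(conn, "neteff_connectome"))
  out <- local_eff_cpp(conn$W, conn$L, weighted, weighted)
  setNames(as.numeric(out), conn$region_ids)
}

#' Whole-network efficiency
#'
#' Global efficiency of a network is the mean inverse shortest-path distance
#' over all ordered node pairs; local efficiency is the mean over nodes of
#' the efficiency `E(G_i)` of each node's neighborhood subgraph.
#'
#' @inheritParams nodal_global_efficiency
#' @return A list with elements `global` and `local`.
#' @export
network_efficiency <- function(conn, weighted = TRUE) {
  stopifnot(inherits(conn, "neteff_connectome"))
  if (conn$n < 2) {
    abort("network efficiency requires at least 2 nodes",
          class = "neteff_error_efficiency")
  }
  glob <- mean(nodal_global_efficiency(conn, weighted))
  sub_eff <- local_eff_cpp(conn$W, conn$L, weighted, FALSE)
  list(global = glob, local = mean(sub_eff))
}

ideal_min_length <- function(conn) {
  if (all(conn$W == 0)) return(NA_real_)
  min(conn$L[conn$W > 0])
}

#' Normalize raw efficiencies by the ideal fully connected network
#'
#' The ideal network shares the connectome's nodes but is fully connected
#' with every strength at the (post-rescaling) maximum of 1 and every length
#' at the subject's minimum observed edge length; for local efficiency the
#' same construction is applied to each neighborhood subgraph. Raw values
#' never exceed the ideal, so normalized efficiencies lie in `[0, 1]`. An
#' empty graph normalizes to zero.
#'
#' @param raw Raw per-node efficiency vector from the matching connectome.
#' @param conn The `neteff_connectome` the raw values came from (with
#'   strengths rescaled to a unit maximum).
#' @param kind `"global"` or `"local"`.
#' @param weighted Whether `raw` was computed with weighted distances.
#' @return Per-node normalized efficiency vector in `[0, 1]`.
#' @export
normalize_efficiency <- function(raw, conn, kind = c("global", "local"),
                                 weighted = TRUE) {
  kind <- match.arg(kind)
  stopifnot(inherits(conn, "neteff_connectome"), length(raw) == conn$n)
  l_min <- ideal_min_length(conn)
  if (is.na(l_min)) return(setNames(rep(0, conn$n), conn$region_ids))
  ideal <- if (kind == "global") {
    # complete ideal graph: every pair at distance l_min
    rep(1 / l_min, conn$n)
  } else {
    # complete ideal neighborhood: weighted term ((1/l_min)*1*1)^(1/3)
    per_node <- if (weighted) l_min^(-1 / 3) else 1 / l_min
    rep(per_node, conn$n)
  }
  out <- raw / ideal
  out[raw == 0] <- 0
  setNames(out, conn$region_ids)
}

#' Normalized efficiency table for a cohort
#'
#' For each subject's connectome: strengths are rescaled to a unit maximum,
#' raw nodal global and nodal local efficiencies are computed, and each is
#' normalized against the ideal fully connected network. Returns the tidy
#' subjects-by-regions table consumed by [fit_region_models()].
#'
#' @param connectomes Named list of `neteff_connectome`s (names are subject
#'   ids) or a single connectome.
#' @param weighted Use weighted (strength-informed) distances (default
#'   `TRUE`).
#' @return A tibble of class `neteff_efficiency` with columns `subject_id`,
#'   `region_id`, `nodal_global`, `nodal_local`, `weighted`.
#' @export
compute_efficiency <- function(connectomes, weighted = TRUE) {
  if (inherits(connectomes, "neteff_connectome")) {
    connectomes <- list(subject = connectomes)
  }
  if (is.null(names(connectomes)) || any(names(connectomes) == "")) {
    abort("connectomes must be a named list (names are subject ids)",
          class = "neteff_error_efficiency")
  }
  rows <- purrr::imap(connectomes, function(conn, sid) {
    conn <- rescale_weights(conn)
    g <- normalize_efficiency(nodal_global_efficiency(conn, weighted),
                              conn, "global", weighted)
    l <- normalize_efficiency(nodal_local_efficiency(conn, weighted),
                              conn, "local", weighted)
    tibble::tibble(
      subject_id = sid,
      region_id = conn$region_ids,
      nodal_global = as.numeric(g),
      nodal_local = as.numeric(l),
      weighted = weighted
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("neteff_efficiency", class(out))
  out
}

#' Plot the distribution of normalized efficiencies
#'
#' @param object A `neteff_efficiency` table from [compute_efficiency()].
#' @param ... Unused.
#' @return A ggplot: per-measure density of normalized efficiency across
#'   subject-region observations.
#' @export
autoplot.neteff_efficiency <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("nodal_global", "nodal_local"),
                              names_to = "measure", values_to = "efficiency")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$efficiency,
                                     fill = .data$measure)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "normalized efficiency", y = "density",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
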
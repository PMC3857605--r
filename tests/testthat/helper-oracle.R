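# Independent oracles: exhaustive simple-path enumeration for shortest
# distances, and direct transcriptions of the efficiency formulas computed
# from the oracle distances. Deliberately naive; never shares code with the
# package's own path computations.

# all-pairs shortest distances by enumerating every simple path (DFS, no
# pruning); E is an edge-length matrix with Inf for absent edges.
oracle_spd <- function(E) {
  n <- nrow(E)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  nbrs <- lapply(seq_len(n), function(i) {
    which(is.finite(E[i, ]) & seq_len(n) != i)
  })
  for (s in seq_len(n)) {
    visited <- rep(FALSE, n)
    dfs <- function(v, d) {
      if (d < D[s, v]) D[s, v] <<- d
      visited[v] <<- TRUE
      for (u in nbrs[[v]]) {
        if (!visited[u]) dfs(u, d + E[v, u])
      }
      visited[v] <<- FALSE
    }
    dfs(s, 0)
  }
  D
}

oracle_edge_lengths <- function(conn, weighted) {
  E <- ifelse(conn$W > 0, if (weighted) conn$L / conn$W else conn$L, Inf)
  diag(E) <- Inf
  E
}

# (1/(N-1)) * sum_{j != i} 1/d_ij, 1/Inf := 0
oracle_nodal_global <- function(conn, weighted) {
  D <- oracle_spd(oracle_edge_lengths(conn, weighted))
  n <- conn$n
  sapply(seq_len(n), function(i) {
    inv <- 1 / D[i, -i]
    sum(inv[is.finite(D[i, -i]) & D[i, -i] > 0]) / (n - 1)
  })
}

# per-node local efficiency with paths restricted to the neighborhood
# subgraph; weighted terms are ((1/d_jk) w_ij w_ik)^(1/3)
oracle_nodal_local <- function(conn, weighted) {
  n <- conn$n
  sapply(seq_len(n), function(i) {
    nb <- which(conn$W[i, ] > 0)
    m <- length(nb)
    if (m < 2) return(0)
    sub <- connectome(conn$W[nb, nb, drop = FALSE],
                      conn$L[nb, nb, drop = FALSE])
    D <- oracle_spd(oracle_edge_lengths(sub, weighted))
    total <- 0
    for (a in seq_len(m)) {
      for (b in seq_len(m)) {
        if (a == b || !is.finite(D[a, b]) || D[a, b] <= 0) next
        total <- total + if (weighted) {
          ((1 / D[a, b]) * conn$W[i, nb[a]] * conn$W[i, nb[b]])^(1 / 3)
        } else {
          1 / D[a, b]
        }
      }
    }
    total / (m * (m - 1))
  })
}

# closed-form OLS via explicit normal equations: beta, t, two-sided p for
# one named column of the design
oracle_ols <- function(X, y, term) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  k <- match(term, colnames(X))
  tval <- unname(beta[k] / se[k])
  list(beta = unname(beta[k]), t = tval, p = 2 * pt(-abs(tval), df))
}
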
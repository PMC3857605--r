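# Small connectomes built in code, used across test files.

# 3-node chain: A-B and B-C, each 2 mm, unit strengths, no A-C edge.
chain3 <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  L <- 2 * (W > 0)
  connectome(W, L)
}

# complete uniform graph: all strengths 1, all lengths 1.
complete_uniform <- function(n = 4) {
  W <- matrix(1, n, n)
  diag(W) <- 0
  connectome(W, W)
}

# star: hub 1 connected to n leaves, leaves mutually unconnected.
star_graph <- function(n_leaves = 4) {
  n <- n_leaves + 1
  W <- matrix(0, n, n)
  W[1, -1] <- W[-1, 1] <- 1
  L <- 2 * (W > 0)
  connectome(W, L)
}

# random weighted connectome; caller controls the RNG state.
rand_connectome <- function(n, p_edge = 0.5, l_range = c(5, 50),
                            w_range = c(0.2, 1)) {
  repeat {
    A <- matrix(runif(n * n) < p_edge, n, n)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    A <- A | t(A)
    if (any(A)) break
  }
  W <- matrix(0, n, n)
  W[A] <- 0 # placeholder
  wvals <- matrix(runif(n * n, w_range[1], w_range[2]), n, n)
  wvals <- (wvals + t(wvals)) / 2
  lvals <- matrix(runif(n * n, l_range[1], l_range[2]), n, n)
  lvals <- (lvals + t(lvals)) / 2
  W <- ifelse(A, wvals, 0)
  L <- ifelse(A, lvals, 0)
  connectome(W, L)
}

# tiny efficiency table built directly (no connectomes), for model tests
make_eff <- function(values, subject_ids, region_ids,
                     measure = "nodal_local") {
  grid <- expand.grid(region_id = region_ids, subject_id = subject_ids,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("subject_id", "region_id")]
  grid[[measure]] <- values
  tibble::as_tibble(grid)
}
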
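# worked objects and random-instance generators shared across tests

# 3-cell network with a self-arrow on cell 1 (permissive); its printed
# spectrum is {-1, 0, 2} with eigenvectors (1,-2,1), (0,0,1), (1,1,1)
example1_matrix <- rbind(c(1L, 1L, 0L),
                         c(2L, 0L, 0L),
                         c(1L, 1L, 0L))
example1_net <- function() {
  regular_network(example1_matrix, allow_self_arrows = TRUE)
}

# printed 6-cell adjacency table of the vulval-precursor line
vpc_matrix <- rbind(
  c(0L, 2L, 0L, 0L, 0L, 0L),
  c(1L, 0L, 1L, 0L, 0L, 0L),
  c(0L, 1L, 0L, 1L, 0L, 0L),
  c(0L, 0L, 1L, 0L, 1L, 0L),
  c(0L, 0L, 0L, 1L, 0L, 1L),
  c(0L, 0L, 0L, 0L, 2L, 0L)
)

# proportionality up to the canonical unit-norm, first-entry-positive scaling
expect_proportional <- function(v, target, tol = 1e-8) {
  v <- as.numeric(v); target <- as.numeric(target)
  v <- v / sqrt(sum(v^2))
  target <- target / sqrt(sum(target^2))
  if (sum(v * target) < 0) target <- -target
  expect_lt(max(abs(v - target)), tol)
}

# random regular directed network without self-arrows: nu arrows into
# each cell, sources drawn uniformly from the other cells
random_directed_regular <- function(n, nu) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    src <- sample(setdiff(seq_len(n), i), nu, replace = TRUE)
    for (s in src) A[i, s] <- A[i, s] + 1L
  }
  regular_network(A)
}

# random connected undirected k-regular graph (symmetric adjacency, so
# the spectrum is real)
random_symmetric_regular <- function(n, k) {
  repeat {
    g <- igraph::sample_k_regular(n, k)
    if (igraph::is_connected(g)) {
      return(regular_network(as.matrix(igraph::as_adjacency_matrix(g))))
    }
  }
}

# as above, but resampled until the adjacency matrix is comfortably
# diagonalizable; eigenvalues of defective Jacobians are intrinsically
# ill-conditioned, which would dull the dual-route spectrum comparison
random_diagonalizable_regular <- function(n, nu) {
  repeat {
    net <- random_directed_regular(n, nu)
    V <- eigen(net$arrow_counts)$vectors
    if (rcond(V) > 1e-6) return(net)
  }
}

random_rank1_R <- function(scale = 1) {
  outer(stats::runif(2, -scale, scale), stats::runif(2, -scale, scale))
}

# shift Q so that the synchronous state is exactly marginally stable:
# max over adjacency eigenvalues of max Re eig(Q + mu R) becomes 0
marginal_shift <- function(Q, R, mus) {
  g <- max(vapply(mus, function(mu) {
    max(Re(eigen(Q + mu * R, only.values = TRUE)$values))
  }, numeric(1)))
  Q - diag(g, nrow(Q))
}

# ground truth for classifier tests: critical adjacency indices and
# eigenvalue type from a dense eigensolve of the full Jacobian
brute_force_critical <- function(lin, network, spec, tol = 1e-7) {
  J <- assemble_full_jacobian(lin, network)
  e <- eigen(J)
  crit <- which(abs(Re(e$values)) <= tol * max(1, max(Mod(e$values))))
  idx <- integer(0)
  any_imag <- FALSE
  s <- lin$node_dim
  n <- network$n_nodes
  for (c in crit) {
    w <- e$vectors[, c]
    if (max(abs(Im(e$values[c]))) > 1e-7) any_imag <- TRUE
    W <- matrix(w, nrow = s)          # species x cells
    for (j in seq_along(spec$eigenvectors)) {
      Vb <- spec$eigenvectors[[j]]
      fr <- (sum(Mod(Re(W) %*% Vb)^2) + sum(Mod(Im(W) %*% Vb)^2)) /
        sum(Mod(W)^2)
      if (fr > 1e-3) idx <- union(idx, j)
    }
  }
  list(indices = sort(idx), any_imaginary = any_imag,
       any_real = any(abs(Im(e$values[crit])) <= 1e-7),
       n_critical = length(crit))
}
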
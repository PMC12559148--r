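#' Adjacency spectrum of a regular network
#'
#' Computes the eigenvalues of the arrow-count adjacency matrix, clusters
#' numerically coincident eigenvalues into distinct values
#' `mu_1 < ... < mu_k` ordered by real part, and records for each cluster
#' its algebraic multiplicity, an orthonormal basis of the real eigenspace
#' `P^mu`, and a basis of the real generalized eigenspace `G^mu` (kernel
#' of `(A - mu I)^n`, computed by rank-revealing SVD rather than a Jordan
#' decomposition).  For a strongly connected network the top eigenvalue is
#' the valence with the all-ones eigenvector; networks without self-arrows
#' have zero-trace spectra, so a negative-real-part eigenvalue always
#' exists.
#'
#' Non-real spectra are flagged (`is_real_spectrum = FALSE`) rather than
#' rejected; the bifurcation classifiers refuse them because the
#' pattern-space enumeration assumes real adjacency eigenvalues.
#'
#' @param network a [regular_network].
#' @param cluster_tol relative clustering tolerance; eigenvalues within
#'   `cluster_tol * max(1, spectral_radius)` of each other are merged.
#'   Integer adjacency tables are additionally snapped to integers when
#'   every eigenvalue is within `1e-6` of one, which keeps the exact
#'   lattice spectra from splitting into spurious clusters.
#' @return An object of class `spectral_data` with fields `eigenvalues`
#'   (complex vector, one per cluster), `multiplicities`, `eigenvectors`
#'   (list of basis matrices of each `P^mu`), `generalized_bases`,
#'   `is_real_spectrum`, `spectral_radius`, `valence`, `n_nodes`,
#'   `strongly_connected`, `has_self_arrows`.
#' @examples
#' spec <- adjacency_spectrum(build_line_lattice(6))
#' Re(spec$eigenvalues)
#' @export
adjacency_spectrum <- function(network, cluster_tol = 1e-8) {
  stopifnot(is_regular_network(network), cluster_tol > 0)
  A <- network$arrow_counts
  n <- network$n_nodes
  ev <- eigen(A, only.values = TRUE)$values
  rho <- max(Mod(ev))
  scale <- max(1, rho)
  is_real <- max(abs(Im(ev))) < cluster_tol * scale
  vals <- if (is_real) Re(ev) else ev

  # integer snapping for exact integer spectra of lattice fixtures
  if (is_real && all(abs(vals - round(vals)) < 1e-6)) {
    vals <- round(vals)
  }

  ord <- order(Re(vals), Im(vals))
  vals <- vals[ord]
  # cluster by real part (ties in imaginary part kept separate)
  tol <- cluster_tol * scale
  cl <- integer(n)
  cl[1L] <- 1L
  for (i in seq_len(n)[-1L]) {
    cl[i] <- if (abs(vals[i] - vals[i - 1L]) <= tol) cl[i - 1L] else cl[i - 1L] + 1L
  }
  k <- cl[n]
  mus <- vapply(seq_len(k), function(j) mean(vals[cl == j]), vals[1L] * 0)
  alphas <- vapply(seq_len(k), function(j) sum(cl == j), integer(1L))

  eigvecs <- vector("list", k)
  genbases <- vector("list", k)
  if (is_real) {
    for (j in seq_len(k)) {
      M <- A - diag(Re(mus[j]), n)
      eigvecs[[j]] <- canonical_basis(null_space(M, tol = 1e-7 * scale))
      Gm <- M
      for (p in seq_len(min(alphas[j], n) - 1L)) Gm <- Gm %*% M
      genbases[[j]] <- canonical_basis(
        null_space(Gm, tol = 1e-7 * max(1, norm(Gm, "2")))
      )
    }
  } else {
    full <- eigen(A)
    for (j in seq_len(k)) {
      sel <- which(abs(full$values[ord][cl == j][1L] - full$values) <= tol)
      eigvecs[[j]] <- full$vectors[, sel, drop = FALSE]
      genbases[[j]] <- eigvecs[[j]]
    }
  }

  structure(
    list(
      eigenvalues = mus,
      multiplicities = alphas,
      eigenvectors = eigvecs,
      generalized_bases = genbases,
      is_real_spectrum = is_real,
      spectral_radius = rho,
      valence = network$valence,
      n_nodes = n,
      strongly_connected = is_strongly_connected(network),
      has_self_arrows = network$has_self_arrows
    ),
    class = "spectral_data"
  )
}

#' @export
print.spectral_data <- function(x, ...) {
  cat(sprintf("spectral_data: %d cells, %d distinct eigenvalues%s\n",
              x$n_nodes, length(x$eigenvalues),
              if (x$is_real_spectrum) "" else " (non-real spectrum)"))
  print(data.frame(
    mu = if (x$is_real_spectrum) Re(x$eigenvalues) else x$eigenvalues,
    multiplicity = x$multiplicities,
    eigenspace_dim = vapply(x$eigenvectors, ncol, integer(1L))
  ))
  invisible(x)
}

# Orthonormal null-space basis of a real matrix via SVD.
null_space <- function(M, tol = 1e-8) {
  sv <- svd(M, nu = 0L)
  rank <- sum(sv$d > tol * max(1, sv$d[1L]))
  if (rank == ncol(M)) {
    return(matrix(numeric(0), nrow = ncol(M), ncol = 0L))
  }
  sv$v[, (rank + 1L):ncol(M), drop = FALSE]
}

# Fix the sign convention: unit columns with first nonzero entry positive,
# so one-dimensional spaces compare directly against printed vectors.
canonical_basis <- function(B) {
  if (ncol(B) == 0L) return(B)
  apply(B, 2L, function(v) {
    v <- v / sqrt(sum(v^2))
    nz <- which(abs(v) > 1e-10)[1L]
    if (!is.na(nz) && v[nz] < 0) v <- -v
    v
  })
}

#' Linearized cell dynamics at a synchronous point
#'
#' Bundles the internal dynamics `Q` (derivative of the cell rate function
#' with respect to the cell's own state) and the coupled dynamics `R`
#' (derivative with respect to a single input arrow's source state), both
#' evaluated on the synchronous branch.  The Jacobian of the full system
#' at a synchronous point decomposes into the reduced matrices
#' `Q + mu_j R` over the adjacency eigenvalues `mu_j`.
#'
#' @param Q,R square numeric matrices of equal size `s` (the number of
#'   chemical species per cell).  Scalars are accepted for `s = 1`.
#' @param x0,lambda0 optional metadata recording the synchronous state and
#'   parameter value at which the derivatives were taken.
#' @return An object of class `linearization`.
#' @export
linearization <- function(Q, R, x0 = NULL, lambda0 = NULL) {
  Q <- as.matrix(Q); R <- as.matrix(R)
  if (!all(dim(Q) == dim(R)) || nrow(Q) != ncol(Q)) {
    stop("Q and R must be square matrices of equal size")
  }
  structure(
    list(Q = Q, R = R, node_dim = nrow(Q), x0 = x0, lambda0 = lambda0),
    class = "linearization"
  )
}

#' @export
print.linearization <- function(x, ...) {
  cat(sprintf("linearization: s = %d\nQ:\n", x$node_dim))
  print(x$Q); cat("R (per input arrow):\n"); print(x$R)
  invisible(x)
}

#' Jacobian spectrum via reduced matrices
#'
#' The Jacobian of any admissible system at a synchronous point has block
#' structure `I (x) Q + A (x) R` ("(x)" the Kronecker product), so its
#' eigenvalues are exactly the union over adjacency eigenvalues `mu_j` of
#' the eigenvalues of the `s x s` reduced matrices `Q + mu_j R`, and its
#' eigenvectors are Kronecker composites of a cell-level vector `u` with a
#' network-level adjacency eigenvector `v_j`.
#'
#' @param lin a [linearization].
#' @param spec a [adjacency_spectrum] result for the same network.
#' @return A list of eigenpairs, each with fields `eigenvalue`,
#'   `cell_part` (length-`s` eigenvector of the reduced matrix),
#'   `mu_index` (cluster index `j`), `network_basis` (basis of `P^mu_j`),
#'   and `multiplicity` (the algebraic multiplicity `alpha_j`).  Counting
#'   multiplicity, the eigenvalues enumerate all `n * s` Jacobian
#'   eigenvalues.
#' @export
jacobian_spectrum <- function(lin, spec) {
  stopifnot(inherits(lin, "linearization"), inherits(spec, "spectral_data"))
  s <- lin$node_dim
  out <- list()
  for (j in seq_along(spec$eigenvalues)) {
    mu <- spec$eigenvalues[j]
    red <- lin$Q + (if (is.complex(mu)) mu else Re(mu)) * lin$R
    e <- eigen(red)
    for (i in seq_len(s)) {
      out[[length(out) + 1L]] <- list(
        eigenvalue = e$values[i],
        cell_part = e$vectors[, i],
        mu_index = j,
        network_basis = spec$eigenvectors[[j]],
        multiplicity = spec$multiplicities[j]
      )
    }
  }
  out
}

#' Full Jacobian of an admissible system at a synchronous point
#'
#' Assembles the dense `(n s) x (n s)` Jacobian directly from its block
#' structure (diagonal blocks `Q`, off-diagonal block `(i, j)` equal to
#' `arrow_counts[i, j] * R`), with cell-major state ordering.  This is the
#' brute-force counterpart of [jacobian_spectrum] and is used as its
#' independent check.
#'
#' @inheritParams jacobian_spectrum
#' @param network the [regular_network] the linearization refers to.
#' @return A numeric matrix `I (x) Q + A (x) R` (cell-major: the state of
#'   cell `i` occupies rows `(i-1)*s + 1:s`).
#' @export
assemble_full_jacobian <- function(lin, network) {
  stopifnot(inherits(lin, "linearization"), is_regular_network(network))
  n <- network$n_nodes
  kronecker(diag(n), lin$Q) + kronecker(network$arrow_counts, lin$R)
}

#' Critical pattern space
#'
#' The critical pattern space is the direct sum of the adjacency
#' eigenspaces `P^mu_j` over the critical index set: the network-level
#' shape of the pattern emerging at a bifurcation.  For index `k` (the
#' valence eigenvalue) this is the all-ones, fully synchronous direction.
#'
#' @param spec a [adjacency_spectrum] result.
#' @param critical_indices nonempty integer vector of cluster indices.
#' @return Matrix whose columns form an orthonormal basis of the direct
#'   sum of the selected eigenspaces.
#' @export
critical_pattern_space <- function(spec, critical_indices) {
  stopifnot(inherits(spec, "spectral_data"))
  critical_indices <- unique(as.integer(critical_indices))
  if (length(critical_indices) == 0L) {
    stop("critical index set must be nonempty")
  }
  if (any(critical_indices < 1L | critical_indices > length(spec$eigenvalues))) {
    stop("critical index out of range")
  }
  do.call(cbind, spec$eigenvectors[critical_indices])
}
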
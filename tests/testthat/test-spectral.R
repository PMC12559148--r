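test_that("worked 3-cell spectrum is reproduced exactly", {
  spec <- adjacency_spectrum(example1_net())
  expect_equal(Re(spec$eigenvalues), c(-1, 0, 2))
  expect_equal(spec$multiplicities, c(1L, 1L, 1L))
  expect_true(spec$is_real_spectrum)
  expect_proportional(spec$eigenvectors[[1]], c(1, -2, 1))
  expect_proportional(spec$eigenvectors[[2]], c(0, 0, 1))
  expect_proportional(spec$eigenvectors[[3]], c(1, 1, 1))
})

test_that("6-cell line has smallest eigenvalue -2 with the alternating eigenvector", {
  spec <- adjacency_spectrum(build_line_lattice(6))
  expect_equal(Re(spec$eigenvalues[1]), -2)
  expect_proportional(spec$eigenvectors[[1]], c(1, -1, 1, -1, 1, -1))
})

test_that("strongly connected networks have the valence as a simple top eigenvalue with all-ones eigenvector", {
  set.seed(11)
  nets <- c(
    list(build_line_lattice(5),
         build_periodic_lattice_2d(4, 4, c(nearest = 1))),
    lapply(1:5, function(i) random_directed_regular(sample(3:8, 1), sample(2:4, 1)))
  )
  for (net in nets) {
    if (!is_strongly_connected(net)) next
    spec <- adjacency_spectrum(net)
    k <- length(spec$eigenvalues)
    expect_equal(Re(spec$eigenvalues[k]), net$valence, tolerance = 1e-10)
    expect_equal(spec$multiplicities[k], 1L)
    expect_proportional(spec$eigenvectors[[k]], rep(1, net$n_nodes))
    expect_equal(sum(spec$multiplicities), net$n_nodes)
  }
})

test_that("no-self-arrow networks have zero-trace spectra with a negative eigenvalue", {
  set.seed(12)
  for (i in 1:5) {
    net <- random_directed_regular(sample(4:8, 1), sample(2:3, 1))
    spec <- adjacency_spectrum(net)
    expect_lt(abs(sum(spec$multiplicities * Re(spec$eigenvalues))), 1e-8)
    expect_lt(Re(spec$eigenvalues[1]), 0)
  }
})

test_that("reduced matrices reproduce the parameterized Jacobian spectrum of the worked system", {
  spec <- adjacency_spectrum(example1_net())
  for (lam in c(0, 0.7, 1.5, 2)) {
    lin <- linearization(-3, -2 * lam)
    pairs <- jacobian_spectrum(lin, spec)
    got <- sort(Re(vapply(pairs, `[[`, complex(1), "eigenvalue")))
    expect_equal(got, sort(c(-3 + 2 * lam, -3, -3 - 4 * lam)),
                 tolerance = 1e-10)
    # the lambda-free eigenvalue belongs to the mu = 0 cluster, whose
    # network direction is the third coordinate axis
    fixed <- pairs[[which(vapply(pairs, function(p)
      p$mu_index == 2L, logical(1)))[1]]]
    expect_equal(Re(fixed$eigenvalue), -3, tolerance = 1e-10)
    expect_proportional(fixed$network_basis, c(0, 0, 1))
  }
})

test_that("the full Jacobian of the worked system matches the hand derivative", {
  net <- example1_net()
  lam <- 0.8
  lin <- linearization(-3, -2 * lam)
  J <- assemble_full_jacobian(lin, net)
  expect_equal(unname(J), rbind(
    c(-3 - 2 * lam, -2 * lam, 0),
    c(-4 * lam, -3, 0),
    c(-2 * lam, -2 * lam, -3)
  ))
  expect_equal(sort(Re(eigen(J, only.values = TRUE)$values)),
               sort(c(-3 + 2 * lam, -3, -3 - 4 * lam)), tolerance = 1e-10)
})

test_that("reduced-matrix and dense full-Jacobian spectra agree on random instances", {
  set.seed(21)
  for (i in 1:40) {
    net <- random_diagonalizable_regular(sample(3:8, 1), sample(2:4, 1))
    s <- sample(1:2, 1)
    lin <- linearization(matrix(stats::runif(s^2, -2, 2), s, s),
                         matrix(stats::runif(s^2, -2, 2), s, s))
    spec <- adjacency_spectrum(net)
    red <- unlist(lapply(jacobian_spectrum(lin, spec), function(p)
      rep(p$eigenvalue, p$multiplicity)))
    full <- eigen(assemble_full_jacobian(lin, net), only.values = TRUE)$values
    scale <- max(1, max(Mod(full)))
    expect_lt(max(abs(sort(Re(red)) - sort(Re(full)))), 1e-8 * scale)
    expect_lt(max(abs(sort(abs(Im(red))) - sort(abs(Im(full))))),
              1e-8 * scale)
  }
})

test_that("Kronecker composites are eigenvectors of the full Jacobian", {
  set.seed(22)
  net <- build_line_lattice(6)
  spec <- adjacency_spectrum(net)
  lin <- linearization(matrix(stats::runif(4, -2, 2), 2, 2),
                       matrix(stats::runif(4, -2, 2), 2, 2))
  J <- assemble_full_jacobian(lin, net)
  for (p in jacobian_spectrum(lin, spec)) {
    for (col in seq_len(ncol(p$network_basis))) {
      w <- as.vector(kronecker(p$network_basis[, col], p$cell_part))
      expect_lt(max(Mod(as.vector(J %*% w) - p$eigenvalue * w)),
                1e-8 * sqrt(sum(Mod(w)^2)) * max(1, max(Mod(J))))
    }
  }
})

test_that("R = 0 collapses the Jacobian to n copies of the internal dynamics", {
  net <- build_line_lattice(4)
  Q <- rbind(c(-1, 2), c(0, -2))
  lin <- linearization(Q, matrix(0, 2, 2))
  full <- eigen(assemble_full_jacobian(lin, net), only.values = TRUE)$values
  expect_equal(sort(Re(full)), sort(rep(Re(eigen(Q)$values), 4)),
               tolerance = 1e-10)
})

test_that("critical pattern spaces concatenate the selected eigenspaces", {
  spec <- adjacency_spectrum(build_line_lattice(6))
  b1 <- critical_pattern_space(spec, 1)
  expect_equal(ncol(b1), 1L)
  expect_proportional(b1, c(1, -1, 1, -1, 1, -1))
  bk <- critical_pattern_space(spec, length(spec$eigenvalues))
  expect_proportional(bk, rep(1, 6))
  ball <- critical_pattern_space(spec, seq_along(spec$eigenvalues))
  expect_equal(qr(ball)$rank, 6L)
  expect_error(critical_pattern_space(spec, integer(0)), "nonempty")
})
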
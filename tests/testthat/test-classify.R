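test_that("stability preconditions gate the internal dynamics", {
  expect_length(stability_preconditions(linearization(-3, -1)), 0)
  expect_length(stability_preconditions(
    linearization(rbind(c(-1, -1), c(0, -1)), matrix(0, 2, 2))), 0)
  expect_match(stability_preconditions(linearization(1, -1)), "negative")
  expect_match(stability_preconditions(
    linearization(rbind(c(2, 0), c(0, -1)), matrix(0, 2, 2))), "tr\\(Q\\)")
  expect_error(stability_preconditions(
    linearization(diag(-1, 3), diag(0, 3))), "1 or 2")
})

test_that("one-species trichotomy: the sign of the coupling picks the crossing", {
  spec <- adjacency_spectrum(build_line_lattice(6))
  mu1 <- Re(spec$eigenvalues[1])          # -2
  k <- length(spec$eigenvalues)

  res <- classify_1d(Q_scalar = mu1 * (-1) * -1, R_scalar = -1, spec)
  expect_equal(res$pattern_space_label, "P_mu1")
  expect_true(res$synchrony_breaking)
  expect_equal(res$critical_indices, 1L)

  res <- classify_1d(Q_scalar = -2, R_scalar = 1, spec)  # Q + nu R = 0
  expect_equal(res$pattern_space_label, "P_muk")
  expect_false(res$synchrony_breaking)

  res <- classify_1d(0, 0, spec)
  expect_equal(res$pattern_space_label, "full_space")
  expect_true(res$degenerate)

  expect_error(classify_1d(-1, 0.1, spec), "not at a bifurcation")
})

test_that("exactly one trichotomy outcome fires at any crossing", {
  set.seed(41)
  for (i in 1:50) {
    net <- random_symmetric_regular(sample(c(4, 6, 8), 1), sample(2:3, 1))
    spec <- adjacency_spectrum(net)
    R <- stats::runif(1, -2, 2)
    mus <- Re(spec$eigenvalues)
    # place the crossing at the eigenvalue the theory dictates
    j <- if (abs(R) < 1e-12) 1L else if (R < 0) 1L else length(mus)
    Q <- -mus[j] * R
    res <- classify_1d(Q, R, spec)
    expected <- if (abs(R) < 1e-12) "full_space" else
      if (R < 0) "P_mu1" else "P_muk"
    expect_equal(res$pattern_space_label, expected)
  }
})

test_that("degeneracy statistics match the closed forms for rank-one couplings", {
  # upper-triangular Q with a positive lower-left coupling: B = -b kappa
  Q <- rbind(c(-1, -0.5), c(0, -2)); kappa <- 0.7
  R <- rbind(c(0, 0), c(kappa, 0))
  st <- degeneracy_statistics(linearization(Q, R))
  expect_equal(st$tr_R, 0)
  expect_equal(st$det_R, 0)
  expect_equal(st$B, -Q[1, 2] * kappa)
  expect_gt(st$B, 0)
  expect_equal(unname(st$det_line), c(det(Q), st$B))

  # coupling in the first species only: B = d kappa
  Q2 <- rbind(c(-1, 2), c(0.3, -2))
  R2 <- rbind(c(kappa, 0), c(0, 0))
  st2 <- degeneracy_statistics(linearization(Q2, R2))
  expect_equal(st2$B, Q2[2, 2] * kappa)

  # no coupling: the determinant line is flat at det(Q)
  st3 <- degeneracy_statistics(linearization(Q2, matrix(0, 2, 2)))
  expect_equal(st3$B, 0)
  expect_equal(unname(st3$det_line), c(det(Q2), 0))

  # B recomputed from first principles
  set.seed(42)
  for (i in 1:20) {
    Qr <- matrix(stats::rnorm(4), 2); Rr <- random_rank1_R()
    st <- degeneracy_statistics(linearization(Qr, Rr))
    expect_equal(st$B,
                 sum(diag(Qr)) * sum(diag(Rr)) - sum(diag(Qr %*% Rr)),
                 tolerance = 1e-12)
  }
})

test_that("nondegeneracy certificates evaluate the two inequalities", {
  # zero-trace coupling with stable internal dynamics certifies a single
  # real crossing
  ndg <- ndg_conditions(
    linearization(rbind(c(-1, -1), c(0, -1)), rbind(c(0, 0), c(1, 0))),
    valence = 2)
  expect_true(ndg$single_real_certified)

  # det Q = 1 > |nu B| = 0 certifies an imaginary pair
  ndg2 <- ndg_conditions(
    linearization(diag(-1, 2), rbind(c(0, 0), c(1, 0))), valence = 2)
  expect_true(ndg2$imaginary_pair_certified)

  ndg3 <- ndg_conditions(
    linearization(matrix(0, 2, 2), rbind(c(0, 0), c(1, 0))), valence = 2)
  expect_false(ndg3$imaginary_pair_certified)
  expect_false(ndg3$single_real_certified)
})

test_that("the singular-coupling classifier reproduces the lateral-inhibition row", {
  spec <- adjacency_spectrum(build_line_lattice(6))
  # determinant line 1 + mu/2 vanishes exactly at mu_1 = -2
  lin <- linearization(rbind(c(-1, -1), c(0, -1)),
                       rbind(c(0, 0), c(0.5, 0)))
  res <- classify_2d_detR0(lin, spec)
  expect_equal(res$rule_index, 1L)
  expect_equal(res$pattern_space_label, "P_mu1")
  expect_equal(res$eigenvalue_type, "real")
  expect_equal(res$critical_multiplicity, 1L)
  expect_true(res$synchrony_breaking)
  expect_false(res$degenerate)
  expect_match(paste(res$notes, collapse = " "), "tr\\(Q\\)")
})

test_that("a positive-trace coupling crossing at the valence eigenvalue is a synchrony-preserving oscillation", {
  spec <- adjacency_spectrum(build_line_lattice(6))
  # trace line -2 + mu vanishes at mu_k = 2; determinant stays positive
  lin <- linearization(rbind(c(-1, 2), c(-2, -1)),
                       rbind(c(1, 0), c(0, 0)))
  res <- classify_2d_detR0(lin, spec)
  expect_equal(res$rule_index, 4L)
  expect_equal(res$pattern_space_label, "P_muk")
  expect_equal(res$eigenvalue_type, "imaginary_pair")
  expect_false(res$synchrony_breaking)
})

test_that("vanishing trace and determinant lines saturate the full space", {
  spec <- adjacency_spectrum(build_line_lattice(4))
  lin <- linearization(matrix(0, 2, 2), rbind(c(0, 0), c(1, 0)))
  res <- classify_2d_detR0(lin, spec)
  expect_equal(res$pattern_space_label, "full_space")
  expect_equal(res$rule_index, 15L)
  expect_true(res$degenerate)
})

test_that("classifier rows agree with dense-eigensolve ground truth at marginal stability", {
  set.seed(43)
  n_ok <- 0L
  for (i in 1:60) {
    net <- random_symmetric_regular(sample(c(4, 6, 8), 1), sample(2:3, 1))
    spec <- adjacency_spectrum(net)
    mus <- Re(spec$eigenvalues)
    Q <- marginal_shift(matrix(stats::rnorm(4), 2), R <- random_rank1_R(), mus)
    lin <- linearization(Q, R)
    res <- tryCatch(classify_2d_detR0(lin, spec), error = function(e) NULL)
    if (is.null(res) || res$degenerate) next
    truth <- brute_force_critical(lin, net, spec)
    expect_equal(res$critical_indices, truth$indices)
    if (res$eigenvalue_type == "imaginary_pair") {
      expect_true(truth$any_imaginary)
    } else if (res$eigenvalue_type == "real") {
      expect_true(truth$any_real)
    }
    n_ok <- n_ok + 1L
  }
  expect_gt(n_ok, 30L)
})

test_that("nonpositive coupling determinants confine criticality to the extreme eigenvalues", {
  set.seed(44)
  for (i in 1:40) {
    net <- random_symmetric_regular(sample(c(4, 6), 1), 2)
    spec <- adjacency_spectrum(net)
    mus <- Re(spec$eigenvalues)
    R <- matrix(stats::rnorm(4), 2)
    if (det(R) > 0) R[, 1] <- -R[, 1]
    Q <- marginal_shift(matrix(stats::rnorm(4), 2), R, mus)
    truth <- brute_force_critical(linearization(Q, R), net, spec)
    expect_true(all(truth$indices %in% c(1L, length(mus))))
  }
  expect_setequal(feasible_pattern_spaces(-0.5),
                  c("P_mu1", "P_muk", "P_mu1_plus_P_muk", "full_space"))
  expect_setequal(feasible_pattern_spaces(0),
                  c("P_mu1", "P_muk", "P_mu1_plus_P_muk", "full_space"))
  expect_equal(feasible_pattern_spaces(1), "any_eigenspace_combination")
})

test_that("certificates never contradict the reported eigenvalue type", {
  set.seed(45)
  for (i in 1:40) {
    net <- random_symmetric_regular(6, 2)
    spec <- adjacency_spectrum(net)
    mus <- Re(spec$eigenvalues)
    Q <- marginal_shift(matrix(stats::rnorm(4), 2), R <- random_rank1_R(), mus)
    lin <- linearization(Q, R)
    res <- tryCatch(classify_2d_detR0(lin, spec), error = function(e) NULL)
    if (is.null(res)) next
    ndg <- ndg_conditions(lin, spec$valence)
    if (ndg$imaginary_pair_certified) {
      expect_false(res$eigenvalue_type == "real")
    }
    if (ndg$single_real_certified) {
      expect_false(res$eigenvalue_type == "imaginary_pair")
    }
  }
})

test_that("classifiers refuse networks violating their assumptions", {
  spec_self <- adjacency_spectrum(example1_net())
  expect_equal(classify_1d(-3, -1, spec_self)$pattern_space_label, "refused")
  res <- classify_2d_detR0(
    linearization(diag(-1, 2), rbind(c(0, 0), c(1, 0))), spec_self)
  expect_equal(res$pattern_space_label, "refused")
  expect_match(res$notes, "self-arrow")
})
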
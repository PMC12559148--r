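single_chem_skeleton <- function() sign_skeleton(matrix("?"), matrix("?"))

# one chemical u coupled to an intracellular partner v; only u talks to
# neighbouring cells
partner_skeleton <- function(Q = matrix("?", 2, 2)) {
  sign_skeleton(Q, rbind(c("?", "0"), c("0", "0")),
                variable_names = list(
                  Q = rbind(c("a", "b"), c("c", "d")),
                  R = rbind(c("kappa", "0"), c("0", "0"))))
}

# u in one cell influences v in its neighbours
cross_skeleton <- function(Q = matrix("?", 2, 2)) {
  sign_skeleton(Q, rbind(c("0", "0"), c("?", "0")),
                variable_names = list(
                  Q = rbind(c("a", "b"), c("c", "d")),
                  R = rbind(c("0", "0"), c("kappa", "0"))))
}

forced_sign_of <- function(conc, entry) {
  conc$forced_signs$sign[conc$forced_signs$entry == entry]
}

test_that("one chemical: a steady pattern forces self-decay and neighbour inhibition", {
  conc <- infer_signs(single_chem_skeleton(),
                      observed_outcome("steady_pattern"))
  expect_equal(forced_sign_of(conc, "Q11"), "-")
  expect_equal(forced_sign_of(conc, "R11"), "-")
  expect_length(conc$contradictions, 0)

  # oscillatory outcomes are impossible with one chemical
  for (cat in c("synchronous_oscillation", "oscillating_pattern")) {
    expect_gt(length(infer_signs(single_chem_skeleton(),
                                 observed_outcome(cat))$contradictions), 0)
  }
})

test_that("intracellular partner: the outcome class pins the coupling trace or B", {
  conc_sync <- infer_signs(partner_skeleton(),
                           observed_outcome("synchronous_oscillation"))
  expect_equal(forced_sign_of(conc_sync, "kappa"), "+")

  conc_osc <- infer_signs(partner_skeleton(),
                          observed_outcome("oscillating_pattern"))
  expect_equal(forced_sign_of(conc_osc, "kappa"), "-")

  conc_steady <- infer_signs(partner_skeleton(),
                             observed_outcome("steady_pattern"))
  # nothing individually forced, but d and kappa must share their sign
  expect_false("kappa" %in% conc_steady$forced_signs$entry)
  rel <- conc_steady$forced_relations
  expect_true(any(rel$entry_1 == "d" & rel$entry_2 == "kappa" &
                    rel$product_sign == "+"))

  # asserting that the partner decays then forces inhibition of u by its
  # neighbours' u
  Qd <- matrix("?", 2, 2); Qd[2, 2] <- "-"
  conc_decay <- infer_signs(partner_skeleton(Qd),
                            observed_outcome("steady_pattern"))
  expect_equal(forced_sign_of(conc_decay, "kappa"), "-")
})

test_that("cross-species coupling admits no oscillatory crossing and forces differing signs", {
  for (cat in c("synchronous_oscillation", "oscillating_pattern")) {
    conc <- infer_signs(cross_skeleton(), observed_outcome(cat))
    expect_gt(length(conc$contradictions), 0)
  }
  conc <- infer_signs(cross_skeleton(), observed_outcome("steady_pattern"))
  rel <- conc$forced_relations
  expect_true(any(rel$entry_1 == "b" & rel$entry_2 == "kappa" &
                    rel$product_sign == "-"))
})

test_that("adding a known sign never removes a forced conclusion", {
  base <- infer_signs(partner_skeleton(),
                      observed_outcome("synchronous_oscillation"))
  Qa <- matrix("?", 2, 2); Qa[1, 1] <- "-"
  refined <- infer_signs(partner_skeleton(Qa),
                         observed_outcome("synchronous_oscillation"))
  expect_true(all(paste(base$forced_signs$entry, base$forced_signs$sign) %in%
                    paste(refined$forced_signs$entry,
                          refined$forced_signs$sign)))
  expect_lte(refined$n_survivors, base$n_survivors)
})

test_that("forced conclusions are sound for numeric instantiations", {
  # steady pattern with the partner skeleton: d * kappa > 0 is exactly
  # the sign of the determinant-line slope B, the necessary condition
  set.seed(61)
  for (i in 1:100) {
    d <- stats::runif(1, 0.1, 2) * sample(c(-1, 1), 1)
    kappa <- stats::runif(1, 0.1, 2) * sign(d)        # respect the relation
    a <- -abs(d) - stats::runif(1, 0.1, 1)            # keep tr Q < 0
    Q <- rbind(c(a, stats::rnorm(1)), c(stats::rnorm(1), d))
    R <- rbind(c(kappa, 0), c(0, 0))
    st <- degeneracy_statistics(linearization(Q, R))
    expect_gt(st$B, 0)
    # violating the relation flips B, making the steady pattern impossible
    stv <- degeneracy_statistics(linearization(Q, -R))
    expect_lt(stv$B, 0)
  }
})

test_that("an interior pattern space forces a positive coupling determinant", {
  spec <- adjacency_spectrum(build_periodic_lattice_2d(
    6, 6, c(nearest = 3, diagonal = 1)))
  k <- length(spec$eigenvalues)
  stripe <- infer_from_pattern_space(
    observed_outcome("steady_pattern", pattern_space_id = 3L), spec)
  expect_equal(stripe$det_R_constraint, "> 0")

  low <- infer_from_pattern_space(
    observed_outcome("steady_pattern", pattern_space_id = 1L), spec)
  expect_true(is.na(low$det_R_constraint))
  expect_false(low$synchrony_preserving)

  top <- infer_from_pattern_space(
    observed_outcome("steady_pattern", pattern_space_id = k), spec)
  expect_true(top$synchrony_preserving)

  expect_error(infer_from_pattern_space(
    observed_outcome("steady_pattern", pattern_space_id = k + 1L), spec),
    "out of range")
})

test_that("the lateral-inhibition sign structure classifies qualitatively to the smallest eigenvalue", {
  spec <- adjacency_spectrum(build_line_lattice(6))
  notch <- sign_skeleton(rbind(c("-", "-"), c("0", "-")),
                         rbind(c("0", "0"), c("+", "0")))
  res <- classify_skeleton(notch, spec)
  expect_equal(res$pattern_space_label, "P_mu1")
  expect_equal(res$rule_index, 1L)
  expect_equal(res$eigenvalue_type, "real")
  expect_true(res$synchrony_breaking)
  expect_match(paste(res$notes, collapse = " "), "tr\\(Q\\) < 0")

  # an all-unknown coupling is ambiguous
  vague <- sign_skeleton(rbind(c("-", "?"), c("?", "-")),
                         rbind(c("?", "0"), c("0", "0")))
  expect_equal(classify_skeleton(vague, spec)$pattern_space_label, "refused")
})
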
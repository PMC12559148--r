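#' Stability preconditions for the synchronous branch
#'
#' Necessary conditions on the internal dynamics for the synchronous
#' branch to be stable at any parameter value before the first crossing:
#' with one species per cell, `Q < 0`; with two, `tr(Q) < 0`.  Both follow
#' from the reduced-matrix decomposition together with the fact that a
#' zero-trace adjacency matrix has eigenvalues of both signs.
#'
#' @param lin a [linearization] with `node_dim` 1 or 2.
#' @return Character vector of violated conditions (empty when all hold).
#' @export
stability_preconditions <- function(lin) {
  stopifnot(inherits(lin, "linearization"))
  s <- lin$node_dim
  if (!s %in% c(1L, 2L)) {
    stop("stability preconditions are formulated for 1 or 2 species per cell")
  }
  out <- character(0)
  if (s == 1L) {
    if (lin$Q[1L, 1L] >= 0) {
      out <- c(out, "internal dynamics Q must be negative (one species)")
    }
  } else {
    if (sum(diag(lin$Q)) >= 0) {
      out <- c(out, "tr(Q) must be negative (two species)")
    }
  }
  out
}

pattern_space_labels <- c("P_mu1", "P_muk", "P_mu1_plus_P_muk",
                          "full_space", "refused")

classification_result <- function(pattern_space_label, eigenvalue_type,
                                  critical_multiplicity, synchrony_breaking,
                                  rule_index = NA_integer_,
                                  degenerate = FALSE, critical_indices = integer(0),
                                  notes = character(0)) {
  structure(
    list(
      pattern_space_label = pattern_space_label,
      eigenvalue_type = eigenvalue_type,
      critical_multiplicity = critical_multiplicity,
      synchrony_breaking = synchrony_breaking,
      rule_index = rule_index,
      degenerate = degenerate,
      critical_indices = critical_indices,
      notes = notes
    ),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "classification: %s (%s critical eigenvalue(s), multiplicity %s)\n",
    x$pattern_space_label, x$eigenvalue_type, x$critical_multiplicity
  ))
  cat(sprintf("synchrony-breaking: %s; degenerate: %s%s\n",
              x$synchrony_breaking, x$degenerate,
              if (!is.na(x$rule_index)) {
                sprintf("; rule row %d", x$rule_index)
              } else ""))
  for (nt in x$notes) cat(" -", nt, "\n")
  invisible(x)
}

refuse_network <- function(spec) {
  if (!spec$is_real_spectrum) {
    return("refused: adjacency spectrum is not real; the classification assumes real eigenvalues")
  }
  if (spec$has_self_arrows) {
    return("refused: network has self-arrows (zero-trace assumption violated)")
  }
  if (!spec$strongly_connected) {
    return("refused: network is not strongly connected")
  }
  NULL
}

criticality_tol <- function(lin, spec, tol = 1e-7) {
  red_k <- lin$Q + Re(spec$eigenvalues[length(spec$eigenvalues)]) * lin$R
  tol * max(1, max(Mod(eigen(red_k, only.values = TRUE)$values)))
}

#' One-species trichotomy for the first bifurcation
#'
#' With one species per cell the real parts of the Jacobian eigenvalues
#' lie on the line `Q + u R` over the adjacency eigenvalues' real parts
#' `u`.  When the synchronous branch loses stability, the sign of the
#' coupled dynamics `R` alone decides which eigenvalue crosses first:
#' negative coupling crosses at the smallest adjacency eigenvalue
#' (synchrony-breaking pattern `P_mu1`), positive coupling at the valence
#' eigenvalue (synchrony-preserving), and `R = 0` is fully degenerate
#' (every reduced eigenvalue crosses at once).
#'
#' @param Q_scalar,R_scalar internal and coupled dynamics (scalars).
#' @param spec a [adjacency_spectrum] result; must be a real spectrum of a
#'   strongly connected network without self-arrows.
#' @param tol relative criticality tolerance.
#' @return A `classification_result`.
#' @export
classify_1d <- function(Q_scalar, R_scalar, spec, tol = 1e-7) {
  stopifnot(inherits(spec, "spectral_data"))
  lin <- linearization(Q_scalar, R_scalar)
  bad <- refuse_network(spec)
  if (!is.null(bad)) {
    return(classification_result("refused", "none", 0L, FALSE, notes = bad))
  }
  mus <- Re(spec$eigenvalues)
  k <- length(mus)
  ctol <- criticality_tol(lin, spec, tol)
  crossing <- abs(Q_scalar + mus * R_scalar) <= ctol
  if (!any(crossing)) {
    stop("not at a bifurcation: no reduced eigenvalue is critical at tolerance")
  }
  a1 <- spec$multiplicities[1L]
  if (abs(R_scalar) <= ctol / max(1, max(abs(mus)))) {
    classification_result(
      "full_space", "real", sum(spec$multiplicities), TRUE,
      degenerate = TRUE, critical_indices = seq_len(k),
      notes = "coupled dynamics vanish: every reduced eigenvalue crosses together"
    )
  } else if (R_scalar < 0) {
    classification_result(
      "P_mu1", "real", a1, TRUE, critical_indices = 1L,
      notes = "R < 0: the smallest adjacency eigenvalue crosses first"
    )
  } else {
    classification_result(
      "P_muk", "real", 1L, FALSE, critical_indices = k,
      notes = "R > 0: the valence eigenvalue crosses first (synchrony-preserving)"
    )
  }
}

#' Degeneracy statistics for two-species cells
#'
#' Trace and determinant of the reduced matrices `Q + mu R` as functions
#' of the adjacency eigenvalue `mu`: the trace line
#' `p1(mu) = tr(Q) + mu tr(R)` always, and - when `det(R) = 0` - the
#' determinant line `p2(mu) = det(Q) + mu B` with slope
#' `B = tr(Q) tr(R) - tr(Q R)`.  The signs of `tr(R)` and `B` decide
#' which adjacency eigenvalue each line can vanish at first, which is the
#' whole content of the two-species classification.
#'
#' @param lin a [linearization] with two species.
#' @param tol absolute tolerance for treating `det(R)` as zero.
#' @return A list of class `degeneracy_statistics` with fields `tr_Q`,
#'   `tr_R`, `det_Q`, `det_R`, `B`, `trace_line` (coefficients of `p1`)
#'   and `det_line` (coefficients of `p2`; `NULL` unless `det(R)` is
#'   within tolerance of zero).
#' @export
degeneracy_statistics <- function(lin, tol = 1e-9) {
  stopifnot(inherits(lin, "linearization"))
  if (lin$node_dim != 2L) stop("degeneracy statistics need two species")
  Q <- lin$Q; R <- lin$R
  B <- sum(diag(Q)) * sum(diag(R)) - sum(diag(Q %*% R))
  out <- list(
    tr_Q = sum(diag(Q)), tr_R = sum(diag(R)),
    det_Q = det(Q), det_R = det(R), B = B,
    trace_line = c(intercept = sum(diag(Q)), slope = sum(diag(R))),
    det_line = NULL
  )
  if (abs(out$det_R) <= tol * max(1, sum(abs(R))^2)) {
    out$det_line <- c(intercept = out$det_Q, slope = B)
  }
  structure(out, class = "degeneracy_statistics")
}

#' Nondegeneracy certificates for two-species cells
#'
#' Two sufficient inequalities that pin the type of the critical
#' eigenvalue when `det(R) = 0`, both driven by the valence being the
#' adjacency spectral radius: if `det(Q) > |nu B|` the determinant line is
#' positive at every adjacency eigenvalue, so criticality must be an
#' imaginary pair from a single reduced matrix; if
#' `tr(Q) < -|nu tr(R)|` the trace line is negative everywhere, so
#' criticality must be a single real crossing.
#'
#' @param lin a [linearization] with two species and singular `R`.
#' @param valence the network valence `nu`.
#' @return List with logical fields `imaginary_pair_certified` and
#'   `single_real_certified`.
#' @export
ndg_conditions <- function(lin, valence) {
  stats <- degeneracy_statistics(lin)
  if (is.null(stats$det_line)) {
    stop("nondegeneracy certificates require det(R) = 0")
  }
  # strict inequalities with a small relative margin: at an exact
  # crossing the boundary case det(Q) = |nu B| (or the trace analogue)
  # holds to rounding error and must not certify
  eps_det <- 1e-9 * max(1, abs(stats$det_Q), abs(valence * stats$B))
  eps_tr <- 1e-9 * max(1, abs(stats$tr_Q), abs(valence * stats$tr_R))
  list(
    imaginary_pair_certified = stats$det_Q > abs(valence * stats$B) + eps_det,
    single_real_certified = stats$tr_Q < -abs(valence * stats$tr_R) - eps_tr
  )
}

# Root set of a line evaluated at the clustered eigenvalues, reported
# structurally: "none", "first", "last", or "all" (identically zero).
line_root_set <- function(intercept, slope, mus, tol) {
  vals <- intercept + mus * slope
  roots <- which(abs(vals) <= tol)
  if (length(roots) == 0L) return("none")
  if (length(roots) == length(mus)) return("all")
  if (identical(roots, 1L)) return("first")
  if (identical(roots, length(mus))) return("last")
  "interior"
}

# The det(R) = 0 rule table: each row of the enumeration is keyed by the
# structural root sets of the trace line p1 and the determinant line p2
# over the adjacency eigenvalues.  Rows 1-4 are the nondegenerate cases;
# rows 5-15 require coincidences and are flagged degenerate.
rule_table <- data.frame(
  row = 1:15,
  p1 = c("none", "first", "none", "last", "first", "last", "last", "first",
         "all", "all", "first", "last", "all", "none", "all"),
  p2 = c("first", "none", "last", "none", "first", "last", "first", "last",
         "first", "last", "all", "all", "none", "all", "all"),
  stringsAsFactors = FALSE
)

#' Two-species classifier for singular coupling
#'
#' Classifies the first bifurcation of a two-species admissible system
#' with `det(R) = 0` on a strongly connected network with real adjacency
#' spectrum.  Both the trace and the determinant of the reduced matrices
#' are then lines in `mu`, so each can vanish either nowhere, only at the
#' smallest eigenvalue `mu_1`, only at the valence eigenvalue `mu_k`, or
#' identically; the fifteen feasible combinations form the rule table,
#' and each determines the critical pattern space, the number and type
#' (real versus imaginary pair) of critical eigenvalues, and whether
#' synchrony breaks.  Rows beyond the first four require additional
#' coincidences and are reported with `degenerate = TRUE`.
#'
#' @param lin a [linearization] with two species, evaluated at the
#'   crossing; `det(R)` must vanish within tolerance.
#' @param spec a [adjacency_spectrum] result.
#' @param tol relative criticality tolerance.
#' @return A `classification_result` with `rule_index` set to the
#'   matching row of the rule table.
#' @export
classify_2d_detR0 <- function(lin, spec, tol = 1e-7) {
  stopifnot(inherits(lin, "linearization"), inherits(spec, "spectral_data"))
  if (lin$node_dim != 2L) stop("classifier needs two species per cell")
  bad <- refuse_network(spec)
  if (!is.null(bad)) {
    return(classification_result("refused", "none", 0L, FALSE, notes = bad))
  }
  stats <- degeneracy_statistics(lin)
  if (is.null(stats$det_line)) {
    stop("det(R) is not zero at tolerance; this classifier handles singular coupling only")
  }
  mus <- Re(spec$eigenvalues)
  k <- length(mus)
  alphas <- spec$multiplicities
  ctol <- criticality_tol(lin, spec, tol)
  s1 <- line_root_set(stats$trace_line[1L], stats$trace_line[2L], mus, ctol)
  s2 <- line_root_set(stats$det_line[1L], stats$det_line[2L], mus,
                      ctol * max(1, max(abs(mus))))
  if (s1 == "none" && s2 == "none") {
    stop("not at a bifurcation: neither the trace nor the determinant line vanishes at any adjacency eigenvalue")
  }
  if (s1 == "interior" || s2 == "interior") {
    stop("inconsistent input: a line cannot vanish only at an interior eigenvalue unless the synchronous branch was already unstable")
  }
  hit <- rule_table$row[rule_table$p1 == s1 & rule_table$p2 == s2]
  row <- hit[1L]

  idx_of <- function(set) switch(set, none = integer(0), first = 1L,
                                 last = k, all = seq_len(k))
  j1 <- idx_of(s1); j2 <- idx_of(s2)
  crit <- sort(unique(c(j1, j2)))
  label <- if (setequal(crit, seq_len(k))) {
    "full_space"
  } else if (setequal(crit, 1L)) {
    "P_mu1"
  } else if (setequal(crit, k)) {
    "P_muk"
  } else {
    "P_mu1_plus_P_muk"
  }

  # multiplicity and type: a trace-only root gives alpha_j imaginary
  # pairs, a det-only root gives alpha_j real eigenvalues, a joint root
  # gives 2 alpha_j real eigenvalues
  n_real <- 0L; n_imag_pairs <- 0L
  for (j in crit) {
    in1 <- j %in% j1; in2 <- j %in% j2
    if (in1 && in2) {
      n_real <- n_real + 2L * alphas[j]
    } else if (in2) {
      n_real <- n_real + alphas[j]
    } else {
      n_imag_pairs <- n_imag_pairs + alphas[j]
    }
  }
  type <- if (n_imag_pairs > 0L && n_real > 0L) {
    "mixed"
  } else if (n_imag_pairs > 0L) {
    "imaginary_pair"
  } else {
    "real"
  }

  ndg <- ndg_conditions(lin, spec$valence)
  notes <- sprintf(
    "trace line vanishes at: %s; determinant line vanishes at: %s", s1, s2
  )
  if (row <= 4L) {
    cert <- if (row %in% c(1L, 3L) && ndg$single_real_certified) {
      "nondegeneracy certified by tr(Q) < -|nu tr(R)|"
    } else if (row %in% c(2L, 4L) && ndg$imaginary_pair_certified) {
      "nondegeneracy certified by det(Q) > |nu B|"
    } else {
      "nondegeneracy verified by direct evaluation of both lines at every eigenvalue"
    }
    notes <- c(notes, cert)
  }

  classification_result(
    pattern_space_label = label,
    eigenvalue_type = type,
    critical_multiplicity = n_real + 2L * n_imag_pairs,
    synchrony_breaking = label != "P_muk",
    rule_index = row,
    degenerate = row > 4L,
    critical_indices = crit,
    notes = notes
  )
}

#' Feasible pattern spaces under nonpositive coupling determinant
#'
#' For two-species cells, if `det(R) <= 0` the determinant of the reduced
#' matrices is a concave quadratic in `mu`, so it can first vanish only at
#' the extreme adjacency eigenvalues.  The critical pattern space is then
#' restricted to `P_mu1`, `P_muk`, their sum, or the full space; a
#' pattern identified with an interior eigenspace therefore forces
#' `det(R) > 0` by contraposition.
#'
#' @param det_R determinant of the coupled dynamics.
#' @return Character vector of feasible pattern-space labels.
#' @export
feasible_pattern_spaces <- function(det_R) {
  if (det_R <= 0) {
    c("P_mu1", "P_muk", "P_mu1_plus_P_muk", "full_space")
  } else {
    "any_eigenspace_combination"
  }
}
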
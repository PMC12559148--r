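# --- qualitative sign algebra -------------------------------------------
# signs: "+" = (0, Inf), "-" = (-Inf, 0), "0" = exactly zero,
#        "?" = unknown / indeterminate
sign_add <- function(a, b) {
  if (a == "0") return(b)
  if (b == "0") return(a)
  if (a == "?" || b == "?") return("?")
  if (a == b) a else "?"
}
sign_mul <- function(a, b) {
  if (a == "0" || b == "0") return("0")
  if (a == "?" || b == "?") return("?")
  if (a == b) "+" else "-"
}
sign_neg <- function(a) switch(a, "+" = "-", "-" = "+", a)
sign_sum <- function(xs) Reduce(sign_add, xs, "0")

# a condition "quantity has sign target" is satisfiable under a fully
# assigned skeleton iff the computed sign is the target or indeterminate
sign_satisfiable <- function(computed, target) {
  computed == target || computed == "?"
}

#' Sign skeletons of the linearized dynamics
#'
#' Partial qualitative knowledge of the internal (`Q`) and coupled (`R`)
#' dynamics: each entry is `"+"` (activation), `"-"` (inhibition), `"0"`
#' (no interaction) or `"?"` (unknown).  Skeletons are the input to the
#' inverse analysis, which determines which unknown signs are forced by
#' an observed tissue-level outcome.
#'
#' @param Q_signs,R_signs character matrices (or vectors for one species)
#'   with entries in `+ - 0 ?`.
#' @param variable_names optional character matrix/vector of entry labels
#'   used in reported conclusions (e.g. `a`, `b`, `kappa`).
#' @return An object of class `sign_skeleton`.
#' @export
sign_skeleton <- function(Q_signs, R_signs, variable_names = NULL) {
  Q <- as.matrix(Q_signs); R <- as.matrix(R_signs)
  if (!all(dim(Q) == dim(R)) || nrow(Q) != ncol(Q)) {
    stop("malformed skeleton: Q and R must be square of equal size")
  }
  if (!all(c(Q, R) %in% c("+", "-", "0", "?"))) {
    stop("malformed skeleton: entries must be one of + - 0 ?")
  }
  s <- nrow(Q)
  if (!s %in% c(1L, 2L)) {
    stop("sign inference is implemented for 1 or 2 species per cell")
  }
  if (is.null(variable_names)) {
    variable_names <- list(
      Q = matrix(paste0("Q", outer(seq_len(s), seq_len(s), paste0)), s, s),
      R = matrix(paste0("R", outer(seq_len(s), seq_len(s), paste0)), s, s)
    )
  }
  structure(
    list(Q = Q, R = R, node_dim = s, variable_names = variable_names),
    class = "sign_skeleton"
  )
}

#' @export
print.sign_skeleton <- function(x, ...) {
  cat(sprintf("sign_skeleton: %d species\nQ:\n", x$node_dim))
  print(x$Q, quote = FALSE); cat("R:\n"); print(x$R, quote = FALSE)
  invisible(x)
}

#' Observed tissue-level outcome
#'
#' The outcome classes the inverse analysis can condition on: the tissue
#' stays homogeneous, oscillates in synchrony, oscillates in a spatial
#' pattern, or settles into a steady spatial pattern.  When the pattern
#' has been identified with a specific adjacency eigenspace its cluster
#' index may be supplied for the coupling-determinant deduction.
#'
#' @param category one of `"homogeneous_steady"`,
#'   `"synchronous_oscillation"`, `"oscillating_pattern"`,
#'   `"steady_pattern"`.
#' @param pattern_space_id optional eigenvalue cluster index of the
#'   identified pattern space (patterned categories only).
#' @return An object of class `observed_outcome`.
#' @export
observed_outcome <- function(category, pattern_space_id = NULL) {
  category <- match.arg(category, c("homogeneous_steady",
                                    "synchronous_oscillation",
                                    "oscillating_pattern",
                                    "steady_pattern"))
  if (!is.null(pattern_space_id) &&
      !category %in% c("oscillating_pattern", "steady_pattern")) {
    stop("pattern_space_id only applies to patterned outcome categories")
  }
  structure(list(category = category, pattern_space_id = pattern_space_id),
            class = "observed_outcome")
}

# quantities of the 2-species analysis in sign arithmetic
skeleton_stats <- function(Q, R) {
  list(
    tr_Q = sign_sum(diag(Q)),
    tr_R = sign_sum(diag(R)),
    det_R = sign_add(sign_mul(R[1L, 1L], R[2L, 2L]),
                     sign_neg(sign_mul(R[1L, 2L], R[2L, 1L]))),
    # B = tr(Q) tr(R) - tr(Q R) simplifies entrywise:
    B = sign_sum(c(sign_mul(Q[1L, 1L], R[2L, 2L]),
                   sign_mul(Q[2L, 2L], R[1L, 1L]),
                   sign_neg(sign_mul(Q[1L, 2L], R[2L, 1L])),
                   sign_neg(sign_mul(Q[2L, 1L], R[1L, 2L]))))
  )
}

# outcome -> necessary sign conditions, nondegenerate route only
outcome_conditions <- function(category, s) {
  if (s == 1L) {
    switch(category,
      homogeneous_steady = list(),
      steady_pattern = list(list(
        quantity = "R", target = "-",
        rule = "one-species trichotomy: synchrony-breaking crossing needs negative coupling")),
      synchronous_oscillation = ,
      oscillating_pattern = list(list(
        quantity = "impossible", target = "",
        rule = "one species cannot produce an oscillatory crossing (real line of eigenvalues)"))
    )
  } else {
    switch(category,
      homogeneous_steady = list(),
      synchronous_oscillation = list(list(
        quantity = "tr_R", target = "+",
        rule = "synchrony-preserving oscillation needs a positive-trace coupling (rule row 4)")),
      oscillating_pattern = list(list(
        quantity = "tr_R", target = "-",
        rule = "synchrony-breaking oscillation needs a negative-trace coupling (rule row 2)")),
      steady_pattern = list(list(
        quantity = "B", target = "+",
        rule = "synchrony-breaking steady crossing needs B > 0 (rule row 1)"))
    )
  }
}

#' Infer sign constraints from an observed outcome
#'
#' Enumerates every assignment of `+`, `-`, `0` to the unknown entries of
#' the skeleton, keeps the assignments under which (a) the synchronous
#' branch can be stable before the crossing (`Q < 0` for one species,
#' `tr(Q) < 0` for two) and (b) the observed outcome's necessary
#' conditions are satisfiable, and reports everything common to all
#' survivors: newly forced entry signs, forced pairwise sign relations
#' (such as "product positive" or "signs differ"), or a contradiction
#' when no assignment survives.  Degenerate crossing routes are excluded
#' by default - coincident degeneracies are not expected in biological
#' systems - which is what gives the analysis its deductive power;
#' `include_degenerate = TRUE` drops the outcome conditions that rely on
#' nondegeneracy, weakening the conclusions.
#'
#' The two-species route requires the skeleton's coupling determinant to
#' be structurally zero (one signalling channel between cells), which is
#' what makes both the trace and the determinant of the reduced matrices
#' linear in the adjacency eigenvalue.
#'
#' @param skeleton a [sign_skeleton].
#' @param outcome an [observed_outcome].
#' @param include_degenerate if `TRUE`, do not impose the nondegenerate
#'   outcome conditions.
#' @return An object of class `inference_conclusion` with fields
#'   `forced_signs` (data frame entry/sign), `forced_relations` (data
#'   frame of pairwise products), `contradictions` (character),
#'   `provenance` (character), `n_survivors`.
#' @export
infer_signs <- function(skeleton, outcome, include_degenerate = FALSE) {
  stopifnot(inherits(skeleton, "sign_skeleton"),
            inherits(outcome, "observed_outcome"))
  s <- skeleton$node_dim
  entries <- rbind(
    data.frame(mat = "Q", i = as.vector(row(skeleton$Q)),
               j = as.vector(col(skeleton$Q)),
               sign = as.vector(skeleton$Q),
               name = as.vector(skeleton$variable_names$Q),
               stringsAsFactors = FALSE),
    data.frame(mat = "R", i = as.vector(row(skeleton$R)),
               j = as.vector(col(skeleton$R)),
               sign = as.vector(skeleton$R),
               name = as.vector(skeleton$variable_names$R),
               stringsAsFactors = FALSE)
  )
  unknown <- which(entries$sign == "?")
  choices <- c("+", "-", "0")
  grid <- if (length(unknown) == 0L) {
    matrix(character(0), nrow = 1L, ncol = 0L)
  } else {
    as.matrix(expand.grid(rep(list(choices), length(unknown)),
                          stringsAsFactors = FALSE))
  }

  conds <- outcome_conditions(outcome$category, s)
  if (include_degenerate) conds <- list()
  provenance <- vapply(conds, `[[`, character(1L), "rule")

  stability_rule <- if (s == 1L) {
    "synchronous-branch stability: Q < 0"
  } else {
    "synchronous-branch stability: tr(Q) < 0"
  }
  provenance <- c(stability_rule, provenance)

  det_zero_required <- s == 2L && length(conds) > 0L
  if (det_zero_required) {
    st0 <- skeleton_stats(matrix(skeleton$Q, 2L), matrix(skeleton$R, 2L))
    if (st0$det_R != "0") {
      stop("two-species inference needs a structurally singular coupling (det R = 0 in the skeleton)")
    }
  }

  survives <- logical(nrow(grid))
  assigned <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    e <- entries$sign
    e[unknown] <- grid[g, ]
    Q <- matrix(e[entries$mat == "Q"], s, s)
    R <- matrix(e[entries$mat == "R"], s, s)
    ok <- if (s == 1L) {
      Q[1L, 1L] == "-"
    } else {
      sign_satisfiable(sign_sum(diag(Q)), "-")
    }
    if (ok) {
      st <- if (s == 2L) skeleton_stats(Q, R) else
        list(R = R[1L, 1L], Q = Q[1L, 1L])
      for (cond in conds) {
        val <- if (cond$quantity == "impossible") {
          "impossible"
        } else if (s == 1L) {
          if (cond$quantity == "R") R[1L, 1L] else Q[1L, 1L]
        } else {
          st[[cond$quantity]]
        }
        if (identical(val, "impossible") ||
            !sign_satisfiable(val, cond$target)) {
          ok <- FALSE
          break
        }
      }
    }
    survives[g] <- ok
    if (ok) assigned[[g]] <- e
  }

  survivors <- assigned[survives]
  if (length(survivors) == 0L) {
    why <- vapply(conds, `[[`, character(1L), "rule")
    if (length(why) == 0L) why <- stability_rule
    return(structure(
      list(
        forced_signs = data.frame(entry = character(0), sign = character(0)),
        forced_relations = data.frame(entry_1 = character(0),
                                      entry_2 = character(0),
                                      product_sign = character(0)),
        contradictions = paste("observation impossible under skeleton:", why),
        provenance = provenance,
        n_survivors = 0L
      ),
      class = "inference_conclusion"
    ))
  }

  surv_mat <- do.call(rbind, survivors)

  # forced signs: unknown entries constant across all survivors
  forced <- data.frame(entry = character(0), sign = character(0),
                       stringsAsFactors = FALSE)
  for (u in unknown) {
    vals <- unique(surv_mat[, u])
    if (length(vals) == 1L) {
      forced <- rbind(forced, data.frame(entry = entries$name[u],
                                         sign = vals,
                                         stringsAsFactors = FALSE))
    }
  }

  # forced pairwise relations among entries still individually free
  free <- setdiff(unknown, match(forced$entry, entries$name))
  relations <- data.frame(entry_1 = character(0), entry_2 = character(0),
                          product_sign = character(0),
                          stringsAsFactors = FALSE)
  if (length(free) >= 2L) {
    pairs <- utils::combn(free, 2L)
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1L, p]; b <- pairs[2L, p]
      prods <- unique(mapply(sign_mul, surv_mat[, a], surv_mat[, b]))
      if (length(prods) == 1L && prods %in% c("+", "-")) {
        relations <- rbind(relations, data.frame(
          entry_1 = entries$name[a], entry_2 = entries$name[b],
          product_sign = prods, stringsAsFactors = FALSE))
      }
    }
  }

  structure(
    list(
      forced_signs = forced,
      forced_relations = relations,
      contradictions = character(0),
      provenance = provenance,
      n_survivors = length(survivors)
    ),
    class = "inference_conclusion"
  )
}

#' @export
print.inference_conclusion <- function(x, ...) {
  if (length(x$contradictions) > 0L) {
    cat("CONTRADICTION:", x$contradictions, "\n")
  } else {
    cat(sprintf("inference over %d surviving sign assignments\n",
                x$n_survivors))
    if (nrow(x$forced_signs) > 0L) {
      for (i in seq_len(nrow(x$forced_signs))) {
        cat(sprintf("  forced: %s is %s\n", x$forced_signs$entry[i],
                    x$forced_signs$sign[i]))
      }
    }
    if (nrow(x$forced_relations) > 0L) {
      for (i in seq_len(nrow(x$forced_relations))) {
        r <- x$forced_relations[i, ]
        cat(sprintf("  forced relation: %s * %s %s 0 (signs %s)\n",
                    r$entry_1, r$entry_2,
                    if (r$product_sign == "+") ">" else "<",
                    if (r$product_sign == "+") "equal" else "differ"))
      }
    }
    if (nrow(x$forced_signs) + nrow(x$forced_relations) == 0L) {
      cat("  nothing new is forced\n")
    }
  }
  for (p in x$provenance) cat(" via:", p, "\n")
  invisible(x)
}

#' Coupling-determinant deduction from an identified pattern space
#'
#' For two-species cells a nonpositive coupling determinant confines the
#' critical pattern space to the extreme adjacency eigenspaces (their
#' sum, or the full space in the extremely degenerate case).  If an
#' observed pattern is identified with an interior eigenspace and the
#' fully degenerate case is ruled out, the coupling determinant must be
#' positive.  A pattern at the smallest eigenvalue is consistent with
#' `det(R) <= 0` and forces nothing; the valence eigenspace carries no
#' spatial pattern at all.
#'
#' @param outcome an [observed_outcome] with `pattern_space_id` set.
#' @param spec a [adjacency_spectrum] result with a real spectrum.
#' @return A list with `det_R_constraint` (`"> 0"` or `NA`),
#'   `synchrony_preserving` flag and a human-readable `conclusion`.
#' @export
infer_from_pattern_space <- function(outcome, spec) {
  stopifnot(inherits(outcome, "observed_outcome"),
            inherits(spec, "spectral_data"))
  if (is.null(outcome$pattern_space_id)) {
    stop("pattern_space_id must be provided")
  }
  if (!spec$is_real_spectrum) {
    stop("the deduction assumes a real adjacency spectrum")
  }
  i <- as.integer(outcome$pattern_space_id)
  k <- length(spec$eigenvalues)
  if (i < 1L || i > k) stop("pattern_space_id out of range")
  if (i == k) {
    return(list(det_R_constraint = NA_character_,
                synchrony_preserving = TRUE,
                conclusion = "the valence eigenspace is the fully synchronous direction; no spatial pattern, nothing inferred"))
  }
  if (i == 1L) {
    return(list(det_R_constraint = NA_character_,
                synchrony_preserving = FALSE,
                conclusion = "pattern at the smallest adjacency eigenvalue is consistent with det(R) <= 0; no sign forced"))
  }
  list(det_R_constraint = "> 0",
       synchrony_preserving = FALSE,
       conclusion = "an interior pattern space is infeasible under det(R) <= 0 (barring the fully degenerate case), so det(R) > 0")
}

#' Classify a two-species sign skeleton at a crossing
#'
#' Qualitative counterpart of [classify_2d_detR0]: from the
#' sign-determined trace of `R` and slope `B` of the determinant line it
#' enumerates the rule-table rows consistent with a first crossing and,
#' when unique, returns the predicted pattern space.  This is how a sign
#' structure like the Delta-Notch one (singular coupling, zero coupling
#' trace, `B > 0`) classifies to the smallest-eigenvalue pattern without
#' any numbers.
#'
#' @param skeleton a two-species [sign_skeleton] with structurally
#'   singular coupling.
#' @param spec a [adjacency_spectrum] result (used for refusal checks).
#' @return A `classification_result`; ambiguous sign information yields
#'   `pattern_space_label = "refused"` with the candidate rows in
#'   `notes`.
#' @export
classify_skeleton <- function(skeleton, spec) {
  stopifnot(inherits(skeleton, "sign_skeleton"),
            inherits(spec, "spectral_data"))
  if (skeleton$node_dim != 2L) stop("skeleton classification needs two species")
  bad <- refuse_network(spec)
  if (!is.null(bad)) {
    return(classification_result("refused", "none", 0L, FALSE, notes = bad))
  }
  st <- skeleton_stats(skeleton$Q, skeleton$R)
  if (st$det_R != "0") {
    stop("skeleton classification requires a structurally singular coupling")
  }
  # feasible root sets of each line given its slope sign; the branch is
  # stable before the crossing, so a nonvanishing line stays one-signed
  p1_sets <- switch(st$tr_R,
                    "0" = if (st$tr_Q == "-") "none" else
                      if (st$tr_Q == "0") "all" else c("none", "all"),
                    "+" = c("none", "last"),
                    "-" = c("none", "first"),
                    "?" = c("none", "first", "last", "all"))
  p2_sets <- switch(st$B,
                    "0" = c("none", "all"),
                    "+" = c("none", "first"),
                    "-" = c("none", "last"),
                    "?" = c("none", "first", "last", "all"))
  combos <- expand.grid(p1 = p1_sets, p2 = p2_sets,
                        stringsAsFactors = FALSE)
  combos <- combos[!(combos$p1 == "none" & combos$p2 == "none"), ,
                   drop = FALSE]
  rows <- merge(combos, rule_table)$row
  ndg_rows <- rows[rows <= 4L]
  use <- if (length(ndg_rows) > 0L) ndg_rows else rows
  if (length(use) == 1L) {
    k <- length(spec$eigenvalues)
    key <- rule_table[rule_table$row == use, ]
    idx_of <- function(set) switch(set, none = integer(0), first = 1L,
                                   last = k, all = seq_len(k))
    crit <- sort(unique(c(idx_of(key$p1), idx_of(key$p2))))
    label <- if (setequal(crit, 1L)) "P_mu1" else
      if (setequal(crit, k)) "P_muk" else
        if (setequal(crit, seq_len(k))) "full_space" else "P_mu1_plus_P_muk"
    type <- if (key$p1 != "none" && key$p2 == "none") "imaginary_pair"
      else if (key$p1 == "none") "real" else "mixed"
    alpha1 <- spec$multiplicities[1L]
    mult <- if (use == 1L) alpha1 else if (use == 2L) 2L * alpha1 else
      if (use == 3L) 1L else 2L
    notes <- sprintf("unique nondegenerate rule row %d from sign structure (tr R %s, B %s)",
                     use, st$tr_R, st$B)
    ndg_note <- if (st$tr_R == "0" && st$tr_Q == "-") {
      "nondegeneracy certified qualitatively: tr(Q) < 0 = -|nu tr(R)|"
    } else {
      NULL
    }
    classification_result(label, type, mult,
                          synchrony_breaking = label != "P_muk",
                          rule_index = use, degenerate = use > 4L,
                          critical_indices = crit,
                          notes = c(notes, ndg_note))
  } else {
    classification_result(
      "refused", "none", 0L, FALSE,
      notes = sprintf("sign information is ambiguous between rule rows %s",
                      paste(sort(unique(use)), collapse = ", ")))
  }
}
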
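#' Colorings of network cells
#'
#' A coloring assigns every cell one of `k` colors; it encodes a candidate
#' pattern of synchrony (same-colored cells share a state).  Colors are
#' renumbered by first occurrence, so two colorings that induce the same
#' partition compare equal.
#'
#' @param colors vector (integer, character or factor) with one entry per
#'   cell.
#' @return An object of class `cell_coloring` with fields `color_of`
#'   (integer vector in `1..k`) and `n_colors`.
#' @examples
#' coloring(c(1, 2, 1, 2, 1, 2))
#' @export
coloring <- function(colors) {
  if (anyNA(colors) || length(colors) == 0L) {
    stop("coloring must assign every cell exactly one color")
  }
  ids <- match(colors, unique(colors))
  structure(
    list(color_of = as.integer(ids), n_colors = length(unique(ids))),
    class = "cell_coloring"
  )
}

#' @export
print.cell_coloring <- function(x, ...) {
  cat(sprintf("coloring: %d cells, %d colors\n",
              length(x$color_of), x$n_colors))
  cat(paste(x$color_of, collapse = " "), "\n")
  invisible(x)
}

#' @rdname coloring
#' @param x object to test.
#' @export
is_coloring <- function(x) inherits(x, "cell_coloring")

# n x k 0/1 indicator basis of the polysynchrony subspace in cell space.
# The subspace in full phase space is this basis Kronecker the species
# identity, built on demand by subspace_intersection_dim().
#' Basis of the polysynchrony subspace of a coloring
#'
#' Columns are the 0/1 indicator vectors of the color classes; their span
#' is the set of cell-space vectors constant on each color class.
#'
#' @param col a [coloring].
#' @return An `n x k` matrix.
#' @export
polysynchrony_basis <- function(col) {
  stopifnot(is_coloring(col))
  n <- length(col$color_of)
  B <- matrix(0, n, col$n_colors)
  B[cbind(seq_len(n), col$color_of)] <- 1
  B
}

# input-color multiset signature: row i gives the number of arrows into
# cell i from each color class
input_color_counts <- function(network, col) {
  k <- col$n_colors
  A <- network$arrow_counts
  sig <- matrix(0L, network$n_nodes, k)
  for (c in seq_len(k)) {
    sel <- col$color_of == c
    sig[, c] <- as.integer(rowSums(A[, sel, drop = FALSE]))
  }
  sig
}

#' Balancedness of a coloring
#'
#' A coloring is balanced when any two same-colored cells receive inputs
#' from identically colored cells with the same arrow multiplicities.
#' Balanced colorings are exactly those whose polysynchrony subspace is
#' flow-invariant for every admissible system on the network, so they are
#' the patterns of synchrony that can persist robustly.
#'
#' @param network a [regular_network].
#' @param col a [coloring] covering all cells.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_balanced(build_line_lattice(6), coloring(rep(1:2, 3)))
#' @export
is_balanced <- function(network, col) {
  stopifnot(is_regular_network(network), is_coloring(col))
  if (length(col$color_of) != network$n_nodes) {
    stop("coloring does not cover all cells")
  }
  sig <- input_color_counts(network, col)
  for (c in seq_len(col$n_colors)) {
    rows <- sig[col$color_of == c, , drop = FALSE]
    if (nrow(rows) > 1L &&
        any(rows != rep(rows[1L, ], each = nrow(rows)))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Coarsest balanced refinement of a coloring
#'
#' Standard partition refinement: color classes are repeatedly split by
#' the input-color-multiset signature of their members until every class
#' is homogeneous.  The result is the balanced coloring with the fewest
#' colors among those refining the seed; a balanced seed is returned
#' unchanged, and in the worst case every cell gets its own color.
#'
#' @inheritParams is_balanced
#' @param seed the starting [coloring].
#' @return A balanced [coloring] refining `seed`.
#' @export
coarsest_balanced_refinement <- function(network, seed) {
  stopifnot(is_regular_network(network), is_coloring(seed))
  col <- seed
  repeat {
    sig <- input_color_counts(network, col)
    key <- paste(col$color_of, apply(sig, 1L, paste, collapse = ","))
    refined <- coloring(key)
    if (refined$n_colors == col$n_colors) {
      return(col)
    }
    col <- refined
  }
}

#' Coloring induced by a cell-space vector
#'
#' Cells whose entries agree within `tol * max(abs(vec))` receive the same
#' color.  Applied to an adjacency eigenvector this translates the
#' network-level shape of a critical pattern into a candidate pattern of
#' synchrony; e.g. an alternating-sign eigenvector induces the two-color
#' alternating pattern.
#'
#' @param vec numeric vector, one entry per cell.
#' @param tol relative tolerance for grouping entries.
#' @return A [coloring], colors ordered by first occurrence.
#' @export
coloring_from_vector <- function(vec, tol = 1e-6) {
  stopifnot(is.numeric(vec), tol > 0)
  scale <- max(abs(vec))
  if (scale == 0) {
    return(coloring(rep(1L, length(vec))))
  }
  ids <- integer(length(vec))
  reps <- numeric(0)
  for (i in seq_along(vec)) {
    hit <- which(abs(reps - vec[i]) <= tol * scale)
    if (length(hit) > 0L) {
      ids[i] <- hit[1L]
    } else {
      reps <- c(reps, vec[i])
      ids[i] <- length(reps)
    }
  }
  coloring(ids)
}

#' Dimension of a subspace intersection with a polysynchrony subspace
#'
#' Computes `dim(span(basis) %intersect% Delta)` by rank arithmetic:
#' `dim U + dim W - dim(U + W)`.  Basis vectors of length `n` are
#' intersected with the cell-space polysynchrony subspace; vectors of
#' length `n * s` with its Kronecker extension to `s` species per cell.
#' The two bifurcation-theorem hypotheses are phrased this way: the
#' critical generalized eigenspace must meet the fully synchronous
#' subspace trivially and the pattern's polysynchrony subspace in
#' dimension one.
#'
#' @param basis matrix whose columns span the subspace (or a single
#'   vector).
#' @param col a [coloring].
#' @return Integer intersection dimension.
#' @export
subspace_intersection_dim <- function(basis, col) {
  stopifnot(is_coloring(col))
  U <- as.matrix(basis)
  n <- length(col$color_of)
  W <- polysynchrony_basis(col)
  if (nrow(U) != n) {
    if (nrow(U) %% n != 0L) {
      stop("basis rows must be n or a multiple of n")
    }
    s <- nrow(U) %/% n
    W <- kronecker(W, diag(s))
  }
  rk <- function(M) {
    if (ncol(M) == 0L) return(0L)
    qr(M, tol = 1e-9)$rank
  }
  rk(U) + rk(W) - rk(cbind(U, W))
}
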
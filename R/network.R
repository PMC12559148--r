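#' Regular cell-communication networks
#'
#' A regular network is a directed multigraph in which every cell (node)
#' receives the same number of input arrows; that common in-degree is the
#' *valence* of the network.  Arrows are stored as an integer multiplicity
#' table: `arrow_counts[i, j]` counts the arrows from cell `j` into cell
#' `i`, so each row sums to the valence.  Self-arrows are refused by
#' default because the downstream bifurcation classifiers assume a
#' zero-trace adjacency matrix; a permissive flag exists for worked
#' examples that only exercise the spectral decomposition.
#'
#' @param arrow_counts square matrix of nonnegative integers;
#'   `arrow_counts[i, j]` is the number of arrows from cell `j` to cell `i`.
#' @param node_labels optional character vector of cell names.
#' @param allow_self_arrows if `TRUE`, accept networks with arrows from a
#'   cell to itself.  Such networks are valid for spectrum assembly but are
#'   refused by the pattern classifiers.
#' @return An object of class `regular_network` with fields
#'   `arrow_counts`, `n_nodes`, `valence`, `node_labels`,
#'   `has_self_arrows`.
#' @examples
#' net <- regular_network(rbind(c(0, 2), c(2, 0)))
#' net$valence
#' @export
regular_network <- function(arrow_counts, node_labels = NULL,
                            allow_self_arrows = FALSE) {
  arrow_counts <- as.matrix(arrow_counts)
  if (nrow(arrow_counts) != ncol(arrow_counts) ||
      !is.numeric(arrow_counts) ||
      anyNA(arrow_counts) ||
      any(arrow_counts < 0) ||
      any(arrow_counts != round(arrow_counts))) {
    stop("malformed adjacency: need a square table of nonnegative integers")
  }
  storage.mode(arrow_counts) <- "integer"
  n <- nrow(arrow_counts)
  rs <- rowSums(arrow_counts)
  if (length(unique(rs)) != 1L) {
    stop("not regular: row sums (in-degrees) differ: ",
         paste(rs, collapse = ", "))
  }
  self <- any(diag(arrow_counts) != 0L)
  if (self && !allow_self_arrows) {
    stop("self-arrow present: diagonal of arrow_counts must be zero")
  }
  if (is.null(node_labels)) {
    node_labels <- if (!is.null(rownames(arrow_counts))) {
      rownames(arrow_counts)
    } else {
      paste0("cell", seq_len(n))
    }
  }
  dimnames(arrow_counts) <- list(node_labels, node_labels)
  structure(
    list(
      arrow_counts = arrow_counts,
      n_nodes = n,
      valence = as.integer(rs[1L]),
      node_labels = node_labels,
      has_self_arrows = self
    ),
    class = "regular_network"
  )
}

#' @export
print.regular_network <- function(x, ...) {
  cat(sprintf("regular_network: %d cells, valence %d%s\n",
              x$n_nodes, x$valence,
              if (x$has_self_arrows) " (has self-arrows)" else ""))
  if (x$n_nodes <= 10L) print(x$arrow_counts)
  invisible(x)
}

#' @rdname regular_network
#' @param x object to test.
#' @export
is_regular_network <- function(x) inherits(x, "regular_network")

as_igraph <- function(network) {
  # arrow_counts[i, j] counts j -> i; igraph wants [from, to]
  igraph::graph_from_adjacency_matrix(
    t(network$arrow_counts != 0L) * 1,
    mode = "directed"
  )
}

#' Strong connectivity of a network
#'
#' A network is strongly connected when every ordered pair of cells is
#' joined by a directed path.  The pattern classifiers require this:
#' it guarantees (by Perron-Frobenius) that the largest adjacency
#' eigenvalue equals the valence, is simple, and has the all-ones
#' eigenvector, so the fully synchronous direction is unambiguous.
#'
#' @param network a [regular_network].
#' @return `TRUE` or `FALSE`.
#' @export
is_strongly_connected <- function(network) {
  stopifnot(is_regular_network(network))
  igraph::is_connected(as_igraph(network), mode = "strong")
}

#' Line of cells with doubled end arrows
#'
#' Builds the 1-D lattice used for fields of cells in a row (e.g. the six
#' C. elegans vulval precursor cells): interior cells receive one arrow
#' from each neighbour, and the two end cells receive two arrows from
#' their single neighbour, so every cell has valence 2.
#'
#' @param n number of cells (at least 2).
#' @return A [regular_network] of valence 2.
#' @examples
#' build_line_lattice(6)$arrow_counts
#' @export
build_line_lattice <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 2) {
    stop("n must be an integer >= 2")
  }
  n <- as.integer(n)
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    nb <- c(i - 1L, i + 1L)
    nb <- nb[nb >= 1L & nb <= n]
    w <- if (length(nb) == 1L) 2L else 1L
    A[i, nb] <- w
  }
  regular_network(A)
}

shell_offsets <- list(
  nearest  = list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L)),
  diagonal = list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
)

#' Periodic 2-D lattice of cells
#'
#' Builds a torus (periodic boundary conditions) of `rows` x `cols` cells
#' with couplings to the nearest-neighbour shell (the four offsets
#' left/right/up/down) and optionally the diagonal shell (the four
#' diagonal offsets), each with its own integer arrow multiplicity.
#' Cells are indexed row-major: cell `(r, c)` is node `(r-1)*cols + c`.
#'
#' @param rows,cols lattice extents, both at least 3 so the wrapped
#'   offsets stay distinct.
#' @param shell_weights named integer vector or list with entries drawn
#'   from `nearest` and `diagonal`; e.g. `c(nearest = 3, diagonal = 1)`.
#' @return A symmetric [regular_network] with valence
#'   `sum(4 * shell_weights)`.
#' @examples
#' net <- build_periodic_lattice_2d(4, 4, c(nearest = 1))
#' net$valence
#' @export
build_periodic_lattice_2d <- function(rows, cols,
                                      shell_weights = c(nearest = 1)) {
  if (rows < 3 || cols < 3) {
    stop("degenerate wrap: rows and cols must be >= 3")
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  shell_weights <- unlist(shell_weights)
  if (is.null(names(shell_weights)) ||
      !all(names(shell_weights) %in% names(shell_offsets))) {
    stop("shell_weights must be named with 'nearest' and/or 'diagonal'")
  }
  if (any(shell_weights <= 0) || any(shell_weights != round(shell_weights))) {
    stop("shell weights must be positive integers")
  }
  n <- rows * cols
  idx <- function(r, c) ((r - 1L) %% rows) * cols + ((c - 1L) %% cols) + 1L
  A <- matrix(0L, n, n)
  for (shell in names(shell_weights)) {
    w <- as.integer(shell_weights[[shell]])
    for (off in shell_offsets[[shell]]) {
      for (r in seq_len(rows)) {
        for (c in seq_len(cols)) {
          A[idx(r, c), idx(r + off[1L], c + off[2L])] <-
            A[idx(r, c), idx(r + off[1L], c + off[2L])] + w
        }
      }
    }
  }
  labels <- as.vector(outer(seq_len(cols), seq_len(rows),
                            function(c, r) sprintf("r%dc%d", r, c)))
  regular_network(A, node_labels = labels)
}
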
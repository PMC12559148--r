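# File formats: adjacency CSV (header row of cell labels, integer
# entries), network JSON ({"nodes": [...], "arrows": [[target, source,
# count], ...]}), coloring JSON ({"colors": [...]}), skeleton JSON
# ({"Q": [...], "R": [...]}, entries in + - 0 ?).  All readers validate
# regularity on load.

#' Read and write networks
#'
#' CSV adjacency tables carry a header row of cell labels and integer
#' arrow multiplicities (`[i, j]` counting arrows from cell `j` into cell
#' `i`); JSON networks list `nodes` and `arrows` as
#' `[target, source, count]` triples (1-based).  Both readers validate
#' regularity on load.
#'
#' @param path file path.
#' @param network a [regular_network].
#' @param allow_self_arrows passed to [regular_network].
#' @return The reader returns a [regular_network]; the writers return
#'   `path` invisibly.
#' @export
read_network_csv <- function(path, allow_self_arrows = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  regular_network(as.matrix(df), node_labels = colnames(df),
                  allow_self_arrows = allow_self_arrows)
}

#' @rdname read_network_csv
#' @export
write_network_csv <- function(network, path) {
  utils::write.csv(as.data.frame(network$arrow_counts), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname read_network_csv
#' @export
read_network_json <- function(path, allow_self_arrows = FALSE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(obj$nodes)
  A <- matrix(0L, n, n)
  arrows <- obj$arrows
  if (is.null(dim(arrows))) arrows <- matrix(arrows, ncol = 3L)
  for (r in seq_len(nrow(arrows))) {
    A[arrows[r, 1L], arrows[r, 2L]] <- A[arrows[r, 1L], arrows[r, 2L]] +
      as.integer(arrows[r, 3L])
  }
  regular_network(A, node_labels = as.character(obj$nodes),
                  allow_self_arrows = allow_self_arrows)
}

#' @rdname read_network_csv
#' @export
write_network_json <- function(network, path) {
  A <- network$arrow_counts
  nz <- which(A != 0L, arr.ind = TRUE)
  arrows <- lapply(seq_len(nrow(nz)), function(r) {
    c(nz[r, 1L], nz[r, 2L], A[nz[r, 1L], nz[r, 2L]])
  })
  jsonlite::write_json(
    list(nodes = network$node_labels, arrows = arrows),
    path, auto_unbox = FALSE
  )
  invisible(path)
}

#' Read and write colorings and skeletons
#'
#' Colorings are stored as `{"colors": [c1, ..., cn]}`; sign skeletons as
#' `{"Q": [[...]], "R": [[...]]}` with entries in `+ - 0 ?`.
#'
#' @param path file path.
#' @export
read_coloring_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coloring(obj$colors)
}

#' @rdname read_coloring_json
#' @param col a [coloring].
#' @export
write_coloring_json <- function(col, path) {
  jsonlite::write_json(list(colors = col$color_of), path)
  invisible(path)
}

#' @rdname read_coloring_json
#' @export
read_skeleton_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sign_skeleton(obj$Q, obj$R)
}

#' @rdname read_coloring_json
#' @param skeleton a [sign_skeleton].
#' @export
write_skeleton_json <- function(skeleton, path) {
  jsonlite::write_json(
    list(Q = skeleton$Q, R = skeleton$R), path, matrix = "rowmajor"
  )
  invisible(path)
}

#' Serialize analysis results as JSON reports
#'
#' Flat, deterministic-key JSON for the spectrum and classification
#' objects, suitable for downstream tooling.
#'
#' @param x a `spectral_data` or `classification_result`.
#' @param path output path.
#' @export
write_report <- function(x, path) {
  payload <- if (inherits(x, "spectral_data")) {
    list(
      eigenvalues = Re(x$eigenvalues),
      multiplicities = x$multiplicities,
      valence_check = isTRUE(all.equal(
        max(Re(x$eigenvalues)), as.numeric(x$valence))),
      is_real_spectrum = x$is_real_spectrum
    )
  } else if (inherits(x, "classification_result")) {
    list(
      pattern_space_label = x$pattern_space_label,
      eigenvalue_type = x$eigenvalue_type,
      critical_multiplicity = x$critical_multiplicity,
      synchrony_breaking = x$synchrony_breaking,
      rule_index = x$rule_index,
      degenerate = x$degenerate,
      notes = x$notes
    )
  } else {
    stop("no report serializer for class ", paste(class(x), collapse = "/"))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write the bundled worked-object fixtures to disk
#'
#' Deterministically regenerates the package's worked objects as plain
#' text files: `example1` (the permissive 3-cell network with its linear
#' model constants), `vpc6` (the 6-cell line), `torus16` (the 16 x 16
#' torus with nearest weight 3 and diagonal weight 1), `collier_params`
#' (the lateral-inhibition constants) and `inference_skeletons` (the
#' three partial sign structures of the inverse-analysis walkthrough).
#'
#' @param name fixture name.
#' @param dir output directory.
#' @return Character vector of the files written.
#' @export
generate_fixture <- function(name, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  switch(
    name,
    example1 = {
      net <- regular_network(rbind(c(1L, 1L, 0L), c(2L, 0L, 0L),
                                   c(1L, 1L, 0L)),
                             allow_self_arrows = TRUE)
      write_network_csv(net, p("example1_network.csv"))
      jsonlite::write_json(
        list(model = "example1", Q = -3, R_per_lambda = -2,
             input = "sum"),
        p("example1_model.json"), auto_unbox = TRUE)
      c(p("example1_network.csv"), p("example1_model.json"))
    },
    vpc6 = {
      write_network_csv(build_line_lattice(6L), p("vpc6_network.csv"))
      p("vpc6_network.csv")
    },
    torus16 = {
      write_network_csv(
        build_periodic_lattice_2d(16L, 16L, c(nearest = 3L, diagonal = 1L)),
        p("torus16_network.csv"))
      p("torus16_network.csv")
    },
    collier_params = {
      jsonlite::write_json(
        list(model = "collier", h = 2, K_N = 0.5, K_D = 0.5,
             lambda_range = c(0, 4)),
        p("collier_params.json"), auto_unbox = TRUE)
      p("collier_params.json")
    },
    inference_skeletons = {
      sk <- list(
        single_chemical = sign_skeleton(matrix("?"), matrix("?")),
        intracellular_partner = sign_skeleton(
          matrix("?", 2L, 2L), rbind(c("?", "0"), c("0", "0"))),
        cross_species_coupling = sign_skeleton(
          matrix("?", 2L, 2L), rbind(c("0", "0"), c("?", "0")))
      )
      files <- character(0)
      for (nm in names(sk)) {
        f <- p(paste0("skeleton_", nm, ".json"))
        write_skeleton_json(sk[[nm]], f)
        files <- c(files, f)
      }
      files
    },
    stop("unknown fixture name: ", name)
  )
}
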
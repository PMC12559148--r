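#' Built-in cell models
#'
#' A small registry of admissible rate laws used throughout the package:
#'
#' * `"collier"`: a two-species lateral-inhibition model of Delta-Notch
#'   type.  Delta decays and is Hill-inhibited by the cell's own Notch;
#'   Notch decays and is Hill-activated by the neighbour-averaged Delta,
#'   with the bifurcation parameter `lambda` scaling the activation
#'   strength.  State order is `(D, N)`.  The linearized internal
#'   dynamics are upper triangular with negative diagonal and negative
#'   Delta-from-Notch entry, and the coupling has a single positive
#'   Notch-from-neighbour-Delta entry, so the coupling determinant
#'   vanishes and the classifier applies.  Hill exponents default to 2
#'   and both Hill thresholds to 0.5, on the scale of the synchronous
#'   equilibrium (Delta relaxes to 1 when uncoupled).
#' * `"example1"`: the linear one-species system
#'   `du/dt = -3 u - 2 lambda * (sum of inputs)` on any network, using
#'   the raw-sum input convention; its synchronous equilibrium is 0 for
#'   every `lambda`.
#' * `"single_chem"`: one self-decaying species with inhibitory coupling,
#'   `du/dt = -u - lambda * mean of inputs`; its first crossing is always
#'   synchrony-breaking.
#' * `"cross_coupling"`: two species where the first activates its own
#'   counterpart in neighbouring cells
#'   (`R` proportional to `diag(lambda, 0)`), giving a positive-trace
#'   coupling that crosses at the valence eigenvalue.
#'
#' @param name model name.
#' @param network a [regular_network] to instantiate the model on.
#' @param params optional named list of model constants overriding the
#'   defaults (for `"collier"`: `h`, `K_N`, `K_D`).
#' @return An [ode_family].
#' @export
get_model <- function(name, network, params = list()) {
  switch(
    name,
    collier = {
      p <- utils::modifyList(list(h = 2, K_N = 0.5, K_D = 0.5), params)
      rate <- function(u, v, lambda) {
        D <- u[1L, , drop = TRUE]; N <- u[2L, , drop = TRUE]
        Dbar <- v[1L, , drop = TRUE]
        rbind(1 / (1 + (N / p$K_N)^p$h) - D,
              lambda * (Dbar / p$K_D)^p$h / (1 + (Dbar / p$K_D)^p$h) - N)
      }
      jac <- function(x0, lambda) {
        D <- x0[1L]; N <- x0[2L]
        dhN <- -(p$h / p$K_N) * (N / p$K_N)^(p$h - 1) /
          (1 + (N / p$K_N)^p$h)^2
        dgD <- lambda * (p$h / p$K_D) * (D / p$K_D)^(p$h - 1) /
          (1 + (D / p$K_D)^p$h)^2
        list(Q = rbind(c(-1, dhN), c(0, -1)),
             R = rbind(c(0, 0), c(dgD / network$valence, 0)))
      }
      ode_family(rate, network, 2L, input = "average", jacobian_fn = jac)
    },
    example1 = ode_family(
      function(u, v, lambda) -3 * u - 2 * lambda * v,
      network, 1L, input = "sum",
      jacobian_fn = function(x0, lambda) {
        list(Q = matrix(-3), R = matrix(-2 * lambda))
      }
    ),
    single_chem = ode_family(
      function(u, v, lambda) -u - lambda * v,
      network, 1L, input = "average",
      jacobian_fn = function(x0, lambda) {
        list(Q = matrix(-1), R = matrix(-lambda / network$valence))
      }
    ),
    cross_coupling = ode_family(
      function(u, v, lambda) {
        rbind(-u[1L, ] + lambda * v[1L, ],
              0.5 * u[1L, ] - u[2L, ])
      },
      network, 2L, input = "average",
      jacobian_fn = function(x0, lambda) {
        list(Q = rbind(c(-1, 0), c(0.5, -1)),
             R = rbind(c(lambda / network$valence, 0), c(0, 0)))
      }
    ),
    stop("unknown model: ", name)
  )
}

#' @rdname get_model
#' @export
model_registry <- function() {
  c("collier", "example1", "single_chem", "cross_coupling")
}
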
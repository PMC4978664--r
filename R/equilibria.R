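#' Reaction terms of the model
#'
#' Evaluates the (non-diffusive) reaction part of the model at given state
#' values, with the delayed population supplied explicitly. Vectorized over
#' all state arguments.
#'
#' @param params An [`model_params()`] object.
#' @param N,u Current population density and control value.
#' @param N_lag Delayed population density \eqn{N(t-\tau)}.
#' @return A list with components `dN` and `du`.
#' @examples
#' p <- example_params()
#' reaction_terms(p, N = 0.2, u = 0.2, N_lag = 0.2) # both zero at E*
#' @export
reaction_terms <- function(params, N, u, N_lag = N) {
  p <- params
  list(
    dN = p$r * N * (1 - (p$a1 * N + p$a2 * N_lag) / p$K - p$c * u),
    du = p$b * N_lag - p$a * u
  )
}

#' Constant steady states
#'
#' The model has two spatially constant nonnegative equilibria: extinction
#' \eqn{E_0 = (0,0)} and the positive equilibrium
#' \deqn{N^* = \frac{aK}{a(a_1+a_2) + bcK}, \qquad u^* = \frac{b}{a} N^*.}
#' Diffusion and delay do not move these states because of the no-flux
#' boundary conditions. The denominator is positive for any valid parameter
#' set, so \eqn{E^*} always exists and is strictly positive.
#'
#' @param params An [`model_params()`] object.
#' @return A tibble with one row per equilibrium and columns
#'   `equilibrium` (`"E0"`, `"Estar"`), `N`, `u`, and the reaction residuals
#'   `res_N`, `res_u` (zero up to roundoff).
#' @examples
#' equilibria(example_params()) # Estar = (0.2, 0.2)
#' @export
equilibria <- function(params) {
  p <- params
  Nstar <- p$a * p$K / (p$a * (p$a1 + p$a2) + p$b * p$c * p$K)
  ustar <- p$b / p$a * Nstar
  Nv <- c(0, Nstar)
  uv <- c(0, ustar)
  res <- reaction_terms(p, N = Nv, u = uv, N_lag = Nv)
  tibble(
    equilibrium = c("E0", "Estar"),
    N = Nv, u = uv,
    res_N = res$dN, res_u = res$du
  )
}

#' Ultimate bounds on population and control (dissipativeness)
#'
#' Any nonnegative solution eventually satisfies
#' \eqn{\limsup_t N \le K/a_1} and \eqn{\limsup_t u \le bK/(a a_1)},
#' by comparison with the undelayed logistic equation: the growth term is
#' dominated by \eqn{rN(1 - a_1 N/K)}, and the control equation is linear in
#' \eqn{u} with bounded input. The bounds depend only on the instantaneous
#' self-limitation weight \eqn{a_1}.
#'
#' @param params An [`model_params()`] object.
#' @return A named numeric vector `c(N = K/a1, u = b*K/(a*a1))`.
#' @examples
#' dissipative_bounds(example_params()) # c(N = 0.5, u = 0.5)
#' @export
dissipative_bounds <- function(params) {
  p <- params
  c(N = p$K / p$a1, u = p$b * p$K / (p$a * p$a1))
}

#' Sufficient condition for permanence
#'
#' The system is permanent (uniformly persistent: solutions eventually
#' bounded away from zero and infinity) whenever
#' \eqn{a a_1 > a a_2 + b c K} strictly. In that case the populations
#' eventually stay above the explicit lower bounds
#' \eqn{(K/a_1)\,m/(a a_1)} and \eqn{(bK/(a a_1))\,m/(a a_1)} with margin
#' \eqn{m = a a_1 - a a_2 - b c K}. The condition is sufficient only: a
#' `FALSE` result does not assert non-permanence.
#'
#' @param params An [`model_params()`] object.
#' @return A list with elements `permanent` (logical), `margin`
#'   (\eqn{a a_1 - a a_2 - b c K}) and, when permanent, `lower_bounds`
#'   (named vector for `N` and `u`; `NULL` otherwise).
#' @examples
#' permanence(example_params()) # FALSE, margin -1
#' @export
permanence <- function(params) {
  p <- params
  margin <- p$a * p$a1 - p$a * p$a2 - p$b * p$c * p$K
  permanent <- margin > 0
  lower <- NULL
  if (permanent) {
    frac <- margin / (p$a * p$a1)
    lower <- c(N = p$K / p$a1 * frac,
               u = p$b * p$K / (p$a * p$a1) * frac)
  }
  list(permanent = permanent, margin = margin, lower_bounds = lower)
}
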
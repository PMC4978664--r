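#' Linearization and quadratic expansion at the positive equilibrium
#'
#' Expands the reaction terms around \eqn{E^* = (N^*, u^*)}. Writing
#' \eqn{\varphi_1(0)}, \eqn{\varphi_1(-\tau)}, \eqn{\varphi_2(0)} for the
#' instantaneous population, delayed population and control deviations, the
#' first component has linear part
#' \deqn{-\frac{r a_1}{K} N^* \varphi_1(0) - \frac{r a_2}{K} N^* \varphi_1(-\tau)
#'       + J_{0,12}\,\varphi_2(0)}
#' and exact quadratic part
#' \deqn{-\frac{r a_1}{K}\varphi_1(0)^2 - \frac{r a_2}{K}\varphi_1(0)\varphi_1(-\tau)
#'       - r c\, \varphi_1(0)\varphi_2(0),}
#' (the reaction is a quadratic polynomial, so the expansion is exact); the
#' second component \eqn{b\varphi_1(-\tau) - a\varphi_2(0)} is exactly linear.
#'
#' @section Coupling conventions:
#' The control-coupling entry \eqn{J_{0,12}} admits two conventions:
#' * `coupling = "reduced"` (default): \eqn{J_{0,12} = -c N^*}. This is the
#'   reduced linearization under which the classical closed-form critical
#'   quantities for this model (Hopf frequency 0.348266 and critical delay
#'   5.81966 at the reference parameters) are derived; all per-mode
#'   characteristic coefficients in [mode_coefficients()] default to it.
#' * `coupling = "exact"`: \eqn{J_{0,12} = -r c N^*}, the exact partial
#'   derivative \eqn{\partial F_1/\partial u} of the reaction term. This is
#'   the linearization of the PDE that [simulate_rd()] integrates, and the
#'   one whose predictions (threshold \eqn{\tau_0' \approx 8.60} at the
#'   reference parameters) the simulator reproduces.
#'
#' The two coincide when \eqn{r = 1}. See the package vignette for a full
#' discussion of the discrepancy and its consequences.
#'
#' @param params An [`model_params()`] object.
#' @param coupling `"reduced"` or `"exact"` (see Details).
#' @return A list with elements
#'   `J0` (2x2 instantaneous Jacobian), `J1` (2x2 delayed Jacobian),
#'   `quadratic` (named numeric vector of the three quadratic coefficients
#'   `phi1_sq`, `phi1_phi1lag`, `phi1_phi2` of the first component),
#'   `Nstar`, `ustar`, and `coupling`.
#' @examples
#' linearize(example_params())$J1 # delayed entry -0.24 at the reference set
#' @export
linearize <- function(params, coupling = c("reduced", "exact")) {
  coupling <- match.arg(coupling)
  p <- params
  Nstar <- p$a * p$K / (p$a * (p$a1 + p$a2) + p$b * p$c * p$K)
  ustar <- p$b / p$a * Nstar
  coupl <- if (coupling == "reduced") -p$c * Nstar else -p$r * p$c * Nstar
  J0 <- matrix(c(-p$r * p$a1 / p$K * Nstar, coupl,
                 0, -p$a), 2, 2, byrow = TRUE)
  J1 <- matrix(c(-p$r * p$a2 / p$K * Nstar, 0,
                 p$b, 0), 2, 2, byrow = TRUE)
  quadratic <- c(phi1_sq = -p$r * p$a1 / p$K,
                 phi1_phi1lag = -p$r * p$a2 / p$K,
                 phi1_phi2 = -p$r * p$c)
  list(J0 = J0, J1 = J1, quadratic = quadratic,
       Nstar = Nstar, ustar = ustar, coupling = coupling)
}
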
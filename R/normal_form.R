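#' Critical eigenvector data at a Hopf point
#'
#' At a Hopf point \eqn{(\omega^*, \tau^*)} of spatial mode \eqn{n}, the
#' critical eigenspace of the delayed linearization is spanned by
#' \eqn{q(\theta) = (1, \xi)^T e^{i\omega^*\tau^*\theta}} and its conjugate,
#' with the adjoint eigenfunction \eqn{q^*(s) = M (1, \eta) e^{i\omega^* s \tau^*}}.
#' The components follow from the right and left null vectors of the
#' characteristic matrix:
#' \deqn{\xi = \frac{b e^{-i\omega^*\tau^*}}{i\omega^* + a + d_2 n^2/l^2}, \qquad
#'       \eta = \frac{J_{0,12}}{i\omega^* + a + d_2 n^2/l^2},}
#' where \eqn{J_{0,12}} is the control-coupling entry of the linearization
#' (\eqn{-cN^*} for the reduced coupling), so for the reduced coupling
#' \eqn{\eta = -cN^*/(i\omega^* + a + d_2 n^2/l^2)}. Note the overall sign
#' of \eqn{\eta}: the left null-vector condition forces it, and both
#' eigenvector residuals are verified to `1e-8` on construction. \eqn{M} normalizes the bilinear
#' pairing with the delayed kernel so that \eqn{(q^*, q) = 1}.
#'
#' @param params An [`model_params()`] object.
#' @param hopf One row of [critical_delays()] (elements `n`, `omega`, `tau`).
#' @param coupling `"reduced"` or `"exact"`; see [linearize()]. Must match
#'   the coupling under which `hopf` was computed. The reduced convention is
#'   realizable as a 2x2 delayed system only for the homogeneous mode, so
#'   `n >= 1` requires `coupling = "exact"`.
#' @return An object of class `"rdlf_eigen"`: list with `n`, `omega`, `tau`,
#'   `xi`, `eta`, `M`, `pairing` (the verified \eqn{(q^*,q)}, equal to 1),
#'   and `residuals` (right/left eigenvector residual moduli).
#' @examples
#' p <- example_params()
#' eigen_data(p, critical_delays(p, 0)[1, ])
#' @export
eigen_data <- function(params, hopf, coupling = c("reduced", "exact")) {
  coupling <- match.arg(coupling)
  p <- params
  n <- hopf$n; w <- hopf$omega; tau <- hopf$tau
  if (coupling == "reduced" && n > 0) {
    abort(paste0(
      "The reduced-coupling eigenvector machinery is only realizable for ",
      "the homogeneous mode (n = 0): at n >= 1 the reduced per-mode ",
      "coefficients are not the determinant of any delayed 2x2 system. ",
      "Use coupling = \"exact\" for inhomogeneous modes."),
      class = "rdlf_nf_error")
  }
  lin <- linearize(p, coupling)
  k2 <- n^2 / p$l^2
  den <- 1i * w + p$a + p$d2 * k2
  if (Mod(den) < 1e-12) {
    abort("Degenerate eigenvector denominator.", class = "rdlf_nf_error")
  }
  Eph <- exp(-1i * w * tau)
  xi <- p$b * Eph / den
  eta <- lin$J0[1, 2] / den
  # Delta(i*omega) for mode n
  Delta <- diag(c(1i * w + p$d1 * k2, 1i * w + p$d2 * k2)) - lin$J0 - lin$J1 * Eph
  q <- c(1, xi)
  qs <- c(1, eta)
  res_r <- max(Mod(Delta %*% q))
  res_l <- max(Mod(qs %*% Delta))
  if (res_r > 1e-8 || res_l > 1e-8) {
    abort("Eigenvector residual exceeds 1e-8; is `hopf` a valid Hopf point for this coupling?",
          class = "rdlf_nf_error")
  }
  # normalization (q*, q) = conj(M) (1 + conj(eta) xi + tau e^{-i w tau} (b conj(eta) + J1[1,1]))
  Mbar <- 1 / (1 + Conj(eta) * xi + tau * Eph * (p$b * Conj(eta) + lin$J1[1, 1]))
  M <- Conj(Mbar)
  pairing <- Mbar * (1 + Conj(eta) * xi + tau * Eph * (p$b * Conj(eta) + lin$J1[1, 1]))
  structure(list(n = as.integer(n), omega = w, tau = tau, xi = xi, eta = eta,
                 M = M, pairing = pairing,
                 residuals = c(right = res_r, left = res_l),
                 coupling = coupling),
            class = "rdlf_eigen")
}

#' Center-manifold projection coefficients at a Hopf point
#'
#' Computes the quadratic and cubic projection coefficients
#' \eqn{g_{20}, g_{11}, g_{02} = \bar g_{20}, g_{21}} of the reduced
#' equation on the two-dimensional center manifold, together with the
#' second-order manifold blocks: the particular-solution vectors
#' \eqn{E_1, E_2} (solving the displayed 2x2 complex linear systems) and the
#' evaluations of \eqn{W_{20}(\theta)}, \eqn{W_{11}(\theta)} at
#' \eqn{\theta \in \{0, -1\}}.
#'
#' For inhomogeneous modes (\eqn{n \ge 1}) the quadratic projections vanish,
#' \eqn{g_{20} = g_{11} = 0}, because the square of the cosine eigenfunction
#' is orthogonal to the mode; spatial averages
#' \eqn{(l\pi)^{-1}\int \cos^2(nx/l)\,dx} are resolved in closed form
#' (1 for \eqn{n = 0}, 1/2 otherwise). Results for \eqn{n \ge 1} are
#' returned but flagged unvalidated (`validated = FALSE`): the scalar
#' treatment of the \eqn{\cos^2} profile ignores mode mixing into modes 0
#' and \eqn{2n}.
#'
#' @section Projection schemes:
#' Two conventions are provided (see the vignette for the full story):
#' * `projection = "reference"` (default): the closed-form coefficient set
#'   under which the reference value \eqn{\mathrm{Re}\,c_1(0) \approx -1.43}
#'   for this model is obtained — quadratic projections without the delay
#'   prefactor and manifold denominators \eqn{\omega^*\tau^*}.
#' * `projection = "rederived"`: the package's own reduction in rescaled
#'   time (standard \eqn{z^2/2} expansion, all \eqn{\tau^*} factors
#'   carried). The two schemes always agree in the signs of
#'   \eqn{\mathrm{Re}\,c_1(0)}, \eqn{\mu_2}, \eqn{\beta_2} — the
#'   classification is scheme-independent.
#'
#' @param params An [`model_params()`] object.
#' @param ed An [eigen_data()] object.
#' @param projection `"reference"` or `"rederived"`.
#' @return A list with complex `g20`, `g11`, `g02`, `g21`, vectors `E1`,
#'   `E2`, the W-evaluations `W20_0`, `W20_m1`, `W11_0`, `W11_m1`, and
#'   `validated`.
#' @examples
#' p <- example_params()
#' ed <- eigen_data(p, critical_delays(p, 0)[1, ])
#' g_coefficients(p, ed)$g20
#' @export
g_coefficients <- function(params, ed, projection = c("reference", "rederived")) {
  projection <- match.arg(projection)
  p <- params
  lin <- linearize(p, ed$coupling)
  n <- ed$n; w <- ed$omega; tau <- ed$tau
  xi <- ed$xi; Mbar <- Conj(ed$M)
  k2 <- n^2 / p$l^2
  Eph <- exp(-1i * w * tau)
  fac <- if (n == 0L) 1 else 0.5   # spatial average of cos^2(nx/l)
  q1 <- p$r * p$a1 / p$K
  q2 <- p$r * p$a2 / p$K
  q3 <- p$r * p$c
  # raw quadratic coefficients of the first reaction component on the
  # critical modes: z^2 and z zbar projections
  c20 <- -(q1 + q2 * Eph + q3 * xi)
  c11 <- -2 * (q1 + q3 * Re(xi) + q2 * Re(Eph))
  gpre <- if (projection == "rederived") tau else 1
  g20 <- if (n == 0L) 2 * gpre * Mbar * c20 else 0 + 0i
  g11 <- if (n == 0L) gpre * Mbar * c11 else 0 + 0i
  g02 <- Conj(g20)
  # second-order manifold blocks: particular solutions at frequencies
  # 2 i omega* and 0
  Dmat <- diag(c(p$d1 * k2, p$d2 * k2))
  M1 <- diag(c(2i * w, 2i * w)) + Dmat - lin$J0 - lin$J1 * Eph^2
  M2 <- Dmat - lin$J0 - lin$J1
  det2 <- function(m) m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (Mod(det2(M1)) < 1e-12 || Mod(det2(M2)) < 1e-12) {
    abort("Resonant center-manifold system (singular E1'/E2' matrix).",
          class = "rdlf_nf_error")
  }
  E1 <- solve(M1, c(2 * fac * c20, 0))
  E2 <- solve(M2, c(fac * c11, 0))
  wd <- w * tau
  qv <- function(ph) c(1, xi) * ph    # q(theta) with ph = e^{i w tau theta}
  W20 <- function(ph) (1i * g20 / wd) * qv(ph) +
    (1i * Conj(g02) / (3 * wd)) * Conj(qv(ph)) + E1 * ph^2
  W11 <- function(ph) (-1i * g11 / wd) * qv(ph) +
    (1i * Conj(g11) / wd) * Conj(qv(ph)) + E2
  W20_0 <- W20(1 + 0i); W20_m1 <- W20(Eph)
  W11_0 <- W11(1 + 0i); W11_m1 <- W11(Eph)
  if (projection == "reference") {
    g21 <- -2 * gpre * Mbar * fac *
      (2 * q1 * (W11_0[1] + W20_0[1]) +
         q3 * (W11_0[2] + 0.5 * W20_0[2] + 0.5 * Conj(xi) * W20_0[1] + xi * W11_0[1]) +
         q2 * (Eph * W11_0[2] + 0.5 * W20_0[2] / Eph + 0.5 * Conj(xi) * W20_m1[1]) +
         q2 * xi * W11_m1[1])
  } else {
    c21 <- -(q1 * (2 * W11_0[1] + W20_0[1]) +
               q2 * (W11_m1[1] + 0.5 * W20_m1[1] + Eph * W11_0[1] + 0.5 * W20_0[1] / Eph) +
               q3 * (W11_0[2] + 0.5 * W20_0[2] + xi * W11_0[1] + 0.5 * Conj(xi) * W20_0[1]))
    g21 <- 2 * gpre * Mbar * fac * c21
  }
  list(g20 = g20, g11 = g11, g02 = g02, g21 = g21,
       E1 = E1, E2 = E2,
       W20_0 = W20_0, W20_m1 = W20_m1, W11_0 = W11_0, W11_m1 = W11_m1,
       validated = n == 0L, projection = projection)
}

#' Hopf normal form and bifurcation properties at a critical delay
#'
#' Performs the center-manifold reduction at a Hopf point and assembles the
#' first Lyapunov-type coefficient
#' \deqn{c_1(0) = \frac{i}{2\omega^*\tau^*}\left(g_{20}g_{11} - 2|g_{11}|^2
#'   - \tfrac13 |g_{02}|^2\right) + \frac{g_{21}}{2}}
#' and the three bifurcation indices
#' \deqn{\mu_2 = -\frac{\mathrm{Re}\,c_1(0)}{\mathrm{Re}\,\lambda'(\tau^*)},\quad
#'       \beta_2 = 2\,\mathrm{Re}\,c_1(0),\quad
#'       T_2 = -\frac{\mathrm{Im}\,c_1(0) + \mu_2\,\mathrm{Im}\,\lambda'(\tau^*)}
#'                  {\omega^*\tau^*},}
#' with \eqn{\lambda'(\tau^*)} the crossing speed from [transversality()].
#' The bifurcation is supercritical (periodic orbits exist for
#' \eqn{\tau > \tau^*}) iff \eqn{\mu_2 > 0}; the bifurcating orbit is
#' orbitally asymptotically stable iff \eqn{\beta_2 < 0}; its period
#' increases with the delay iff \eqn{T_2 > 0}.
#'
#' @inheritParams eigen_data
#' @param projection `"reference"` or `"rederived"`; see [g_coefficients()].
#' @return An object of class `"rdlf_nf"` with the eigen data, g
#'   coefficients, `c1`, `lambda_prime`, `mu2`, `beta2`, `T2`, and the
#'   classification strings `direction`, `orbit_stability`, `period_trend`.
#' @examples
#' p <- example_params()
#' nf <- normal_form(p, critical_delays(p, 0)[1, ])
#' glance(nf)
#' @export
normal_form <- function(params, hopf, coupling = c("reduced", "exact"),
                        projection = c("reference", "rederived")) {
  coupling <- match.arg(coupling)
  projection <- match.arg(projection)
  ed <- eigen_data(params, hopf, coupling)
  g <- g_coefficients(params, ed, projection)
  wd <- ed$omega * ed$tau
  c1 <- (1i / (2 * wd)) *
    (g$g20 * g$g11 - 2 * Mod(g$g11)^2 - Mod(g$g02)^2 / 3) + g$g21 / 2
  tv <- transversality(params, hopf, coupling)
  lp <- tv$dlambda_dtau
  if (Re(lp) <= 0) {
    abort("Re(lambda'(tau*)) <= 0: upstream transversality failure.",
          class = "rdlf_nf_error")
  }
  mu2 <- -Re(c1) / Re(lp)
  beta2 <- 2 * Re(c1)
  T2 <- -(Im(c1) + mu2 * Im(lp)) / wd
  structure(list(
    eigen = ed, g = g, c1 = c1, lambda_prime = lp,
    mu2 = mu2, beta2 = beta2, T2 = T2,
    direction = if (mu2 > 0) "supercritical" else "subcritical",
    orbit_stability = if (beta2 < 0) "stable" else "unstable",
    period_trend = if (T2 > 0) "increasing" else "decreasing",
    coupling = coupling, projection = projection,
    validated = g$validated
  ), class = "rdlf_nf")
}

#' @export
print.rdlf_nf <- function(x, ...) {
  ed <- x$eigen
  cat("Hopf normal form at (n = ", ed$n, ", omega = ", format(ed$omega),
      ", tau = ", format(ed$tau), ")\n", sep = "")
  cat("  coupling/projection: ", x$coupling, " / ", x$projection, "\n", sep = "")
  cat("  c1(0)  = ", format(x$c1), "\n", sep = "")
  cat("  mu2    = ", format(x$mu2), "  (", x$direction, ")\n", sep = "")
  cat("  beta2  = ", format(x$beta2), "  (orbit ", x$orbit_stability, ")\n", sep = "")
  cat("  T2     = ", format(x$T2), "  (period ", x$period_trend, ")\n", sep = "")
  if (!x$validated) cat("  [n >= 1: unvalidated spatial-average treatment]\n")
  invisible(x)
}

#' Tidy a Hopf normal-form object
#'
#' @param x An [normal_form()] result.
#' @param ... Unused.
#' @return A tibble with one row per complex coefficient (`g20`, `g11`,
#'   `g02`, `g21`, `c1`, `lambda_prime`) and columns `term`, `real`,
#'   `imaginary`, `modulus`.
#' @export
tidy.rdlf_nf <- function(x, ...) {
  vals <- c(g20 = x$g$g20, g11 = x$g$g11, g02 = x$g$g02, g21 = x$g$g21,
            c1 = x$c1, lambda_prime = x$lambda_prime)
  tibble(term = names(vals), real = Re(vals), imaginary = Im(vals),
         modulus = Mod(vals))
}

#' One-row summary of a Hopf normal-form object
#'
#' @param x An [normal_form()] result.
#' @param ... Unused.
#' @return A one-row tibble with the Hopf point, the three real indices and
#'   the classification strings.
#' @export
glance.rdlf_nf <- function(x, ...) {
  tibble(n = x$eigen$n, omega = x$eigen$omega, tau = x$eigen$tau,
         re_c1 = Re(x$c1), im_c1 = Im(x$c1),
         mu2 = x$mu2, beta2 = x$beta2, T2 = x$T2,
         direction = x$direction, orbit_stability = x$orbit_stability,
         period_trend = x$period_trend,
         coupling = x$coupling, projection = x$projection)
}
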
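#' Characteristic-equation coefficients per spatial mode
#'
#' On the interval \eqn{(0, l\pi)} with no-flux boundaries the Laplacian has
#' eigenvalues \eqn{-n^2/l^2} with cosine eigenfunctions, so the linearization
#' at \eqn{E^*} decomposes into spatial modes \eqn{n = 0, 1, 2, \ldots}, each
#' governed by the transcendental characteristic equation
#' \deqn{\lambda^2 + A_n \lambda + B_n + e^{-\lambda\tau}(C \lambda + D_n) = 0.}
#' This function returns \eqn{A_n, B_n, C, D_n}; all four are strictly
#' positive for valid parameters, and \eqn{C} does not depend on \eqn{n}.
#'
#' With `coupling = "reduced"` (default) the coefficients are the classical
#' closed forms for this model,
#' \deqn{A_n = (d_1+d_2)\frac{n^2}{l^2} + a + \frac{r a_1}{K}N^*, \quad
#'       B_n = d_1 d_2 \frac{n^4}{l^4} + \left(a + \frac{r a_1}{K}N^*\right) d_1 \frac{n^2}{l^2} + \frac{r a a_1}{K}N^*,}
#' \deqn{C = \frac{r a_2}{K}N^*, \quad
#'       D_n = \frac{r a_2}{K}N^* d_1 \frac{n^2}{l^2} + \frac{r a a_2}{K}N^* + b c N^*.}
#' With `coupling = "exact"` they are computed from the determinant of the
#' exact mode-\eqn{n} linearization (see [linearize()]); the two differ in the
#' control-coupling factor entering \eqn{D_n} and in which diffusion
#' coefficient multiplies the cross terms, and they coincide at \eqn{n = 0}
#' when \eqn{r = 1}.
#'
#' @param params An [`model_params()`] object.
#' @param n Vector of nonnegative integer mode indices.
#' @param coupling `"reduced"` or `"exact"`; see [linearize()].
#' @return A tibble with columns `n`, `A`, `B`, `C`, `D`.
#' @examples
#' mode_coefficients(example_params(), 0:2)
#' @export
mode_coefficients <- function(params, n, coupling = c("reduced", "exact")) {
  coupling <- match.arg(coupling)
  stopifnot(all(n >= 0), all(n == floor(n)))
  p <- params
  lin <- linearize(p, coupling)
  Nstar <- lin$Nstar
  k2 <- n^2 / p$l^2
  s1 <- p$r * p$a1 / p$K * Nstar   # instantaneous self-limitation at E*
  C <- p$r * p$a2 / p$K * Nstar    # delayed self-limitation at E*
  A <- (p$d1 + p$d2) * k2 + p$a + s1
  if (coupling == "reduced") {
    B <- p$d1 * p$d2 * k2^2 + (p$a + s1) * p$d1 * k2 + p$a * s1
    D <- C * p$d1 * k2 + p$a * C + p$b * p$c * Nstar
  } else {
    # determinant of (lambda + d1 k^2 - J0[1,1] + C e^{-lambda tau})(lambda + d2 k^2 + a)
    # minus the delayed off-diagonal product
    B <- (p$d1 * k2 + s1) * (p$d2 * k2 + p$a)
    D <- C * (p$d2 * k2 + p$a) - lin$J0[1, 2] * p$b
  }
  tibble(n = as.integer(n), A = A, B = B, C = C, D = D)
}

#' Spectrum of the extinction state
#'
#' At \eqn{E_0 = (0,0)} the linearization is triangular, so each spatial mode
#' contributes the two real eigenvalues
#' \eqn{\lambda_{1,n} = -d_1 n^2/l^2 + r} and
#' \eqn{\lambda_{2,n} = -d_2 n^2/l^2 - a}, independent of the delay. Since
#' \eqn{\lambda_{1,0} = r > 0}, the extinction state is unstable for every
#' valid parameter set and every delay.
#'
#' @param params An [`model_params()`] object.
#' @param n_max Largest mode index to tabulate.
#' @return A tibble with columns `n`, `lambda1`, `lambda2`, carrying the
#'   attribute `verdict = "unstable"`.
#' @examples
#' trivial_spectrum(example_params(), 3)
#' @export
trivial_spectrum <- function(params, n_max) {
  stopifnot(n_max >= 0)
  p <- params
  n <- 0:n_max
  k2 <- n^2 / p$l^2
  out <- tibble(n = n, lambda1 = -p$d1 * k2 + p$r, lambda2 = -p$d2 * k2 - p$a)
  attr(out, "verdict") <- "unstable"
  out
}

#' Candidate Hopf frequencies of one spatial mode
#'
#' A purely imaginary root \eqn{\lambda = i\omega} (\eqn{\omega > 0}) of the
#' mode-\eqn{n} characteristic equation requires
#' \deqn{\omega^4 + (A_n^2 - 2B_n - C^2)\,\omega^2 + B_n^2 - D_n^2 = 0.}
#' The quadratic in \eqn{\omega^2} is formed with
#' \eqn{P_n = A_n^2 - 2B_n - C^2} and \eqn{Q_n = B_n^2 - D_n^2} computed
#' directly from the coefficient values, and all strictly positive real roots
#' \eqn{\omega} are returned (largest first). When \eqn{Q_n < 0} there is
#' exactly one, \eqn{\omega_n = \sqrt{(-P_n + \sqrt{P_n^2 - 4Q_n})/2}}.
#' Roots with \eqn{|Q_n|} within `1e-12` of zero are treated as nonexistent
#' (no Hopf), with a warning.
#'
#' @inheritParams mode_coefficients
#' @param n A single nonnegative mode index.
#' @return Numeric vector of positive frequencies (possibly empty).
#' @examples
#' hopf_frequencies(example_params(), 0) # 0.348266
#' hopf_frequencies(example_params(), 1) # empty
#' @export
hopf_frequencies <- function(params, n, coupling = c("reduced", "exact")) {
  coupling <- match.arg(coupling)
  stopifnot(length(n) == 1L)
  mc <- mode_coefficients(params, n, coupling)
  P <- mc$A^2 - 2 * mc$B - mc$C^2
  Q <- mc$B^2 - mc$D^2
  if (abs(Q) < 1e-12) {
    warn("B_n^2 - D_n^2 is numerically zero; treating as no purely imaginary root.")
    Q <- abs(Q)
  }
  disc <- P^2 - 4 * Q
  if (disc < 0) return(numeric(0))
  x <- c((-P + sqrt(disc)) / 2, (-P - sqrt(disc)) / 2)
  x <- x[x > 1e-12]
  sort(sqrt(x), decreasing = TRUE)
}

#' Largest spatial mode that can destabilize (mode cutoff)
#'
#' Scans \eqn{n = 0, 1, 2, \ldots} for the sign of
#' \eqn{Q_n = B_n^2 - D_n^2}. Modes with \eqn{Q_n < 0} admit a pair of
#' purely imaginary characteristic roots for suitable delays; the cutoff
#' \eqn{N_0} is the largest such mode. Returns `NA` when already
#' \eqn{Q_0 \ge 0} (no mode can destabilize). When \eqn{a_1 \ge a_2} the
#' bracketed factor of \eqn{Q_n} is strictly increasing in \eqn{n^2}, so the
#' sign change is final; for \eqn{a_1 < a_2} the whole range up to `n_max` is
#' scanned. An error is raised if the sign has not stabilized by `n_max`.
#'
#' @inheritParams mode_coefficients
#' @param n_max Safety bound for the scan (default 200).
#' @return Integer \eqn{N_0}, or `NA_integer_` when no mode can destabilize.
#' @examples
#' mode_cutoff(example_params()) # 0
#' @export
mode_cutoff <- function(params, n_max = 200, coupling = c("reduced", "exact")) {
  coupling <- match.arg(coupling)
  stopifnot(n_max >= 1)
  mc <- mode_coefficients(params, 0:n_max, coupling)
  Q <- mc$B^2 - mc$D^2
  tie <- abs(Q) < 1e-12
  if (any(tie)) {
    warn("B_n^2 - D_n^2 within 1e-12 of zero for some mode; classified as >= 0.")
    Q[tie] <- abs(Q[tie])
  }
  neg <- which(Q < 0) - 1L  # mode indices with negative sign
  if (length(neg) == 0L) return(NA_integer_)
  N0 <- max(neg)
  if (N0 == n_max) {
    abort(paste0("Sign of B_n^2 - D_n^2 has not stabilized by n_max = ", n_max,
                 "; increase n_max."), class = "rdlf_spectral_error")
  }
  as.integer(N0)
}

#' Critical delays (Hopf points) of one spatial mode
#'
#' For each candidate frequency \eqn{\omega_n} of mode \eqn{n}, the smallest
#' delay with roots \eqn{\pm i\omega_n} is
#' \deqn{\tau_0^{(n)} = \frac{1}{\omega_n}\arccos
#'   \frac{(D_n - A_n C)\omega_n^2 - B_n D_n}{C^2\omega_n^2 + D_n^2},}
#' valid on the principal branch because \eqn{\sin\omega_n\tau > 0} there
#' (a consequence of \eqn{A_n D_n - B_n C > 0}); if the sine expression is
#' negative the reflected branch \eqn{(2\pi - \arccos\cdot)/\omega_n} is used
#' instead. Subsequent branches repeat with period \eqn{2\pi/\omega_n}:
#' \eqn{\tau_j^{(n)} = \tau_0^{(n)} + 2\pi j/\omega_n}.
#'
#' @inheritParams hopf_frequencies
#' @param j_max Largest branch index \eqn{j} (default 0).
#' @return A tibble of Hopf points with columns `n`, `j`, `omega`, `tau`,
#'   and `residual` (modulus of the characteristic polynomial at
#'   \eqn{(i\omega, \tau)}, zero up to roundoff).
#' @examples
#' critical_delays(example_params(), 0, j_max = 2) # 5.81966, 23.861, 41.9024
#' @export
critical_delays <- function(params, n, j_max = 0,
                            coupling = c("reduced", "exact")) {
  coupling <- match.arg(coupling)
  om <- hopf_frequencies(params, n, coupling)
  if (length(om) == 0L) {
    abort(paste0("No Hopf frequency for mode n = ", n, "."),
          class = "rdlf_spectral_error")
  }
  mc <- mode_coefficients(params, n, coupling)
  out <- purrr::map_dfr(om, function(w) {
    den <- mc$C^2 * w^2 + mc$D^2
    cosv <- ((mc$D - mc$A * mc$C) * w^2 - mc$B * mc$D) / den
    sinv <- (mc$C * w^3 + (mc$A * mc$D - mc$B * mc$C) * w) / den
    tau0 <- if (sinv >= 0) acos(cosv) / w else (2 * pi - acos(cosv)) / w
    tibble(n = as.integer(n), j = 0:j_max, omega = w,
           tau = tau0 + 2 * pi * (0:j_max) / w)
  })
  out$residual <- vapply(seq_len(nrow(out)), function(i) {
    Mod(char_residual(params, n, 1i * out$omega[i], out$tau[i], coupling))
  }, numeric(1))
  out
}

#' Characteristic polynomial residual
#'
#' Evaluates \eqn{\lambda^2 + A_n\lambda + B_n + e^{-\lambda\tau}(C\lambda + D_n)}
#' for mode \eqn{n}. Zero exactly when \eqn{\lambda} is a characteristic
#' root at delay \eqn{\tau}. At \eqn{\lambda = 0} the value is
#' \eqn{B_n + D_n > 0}, so zero is never a root.
#'
#' @inheritParams hopf_frequencies
#' @param lambda Complex value(s) at which to evaluate.
#' @param tau Delay (nonnegative).
#' @return Complex vector of residuals.
#' @examples
#' char_residual(example_params(), 0, 0.348266i, 5.81966) # ~0
#' @export
char_residual <- function(params, n, lambda, tau,
                          coupling = c("reduced", "exact")) {
  coupling <- match.arg(coupling)
  stopifnot(tau >= 0)
  mc <- mode_coefficients(params, n, coupling)
  lambda^2 + mc$A * lambda + mc$B + exp(-lambda * tau) * (mc$C * lambda + mc$D)
}

#' Transversality of an imaginary-axis crossing
#'
#' Differentiating the characteristic equation in \eqn{\tau} along the root
#' branch and evaluating at \eqn{\lambda = i\omega_n}, \eqn{\tau = \tau_j^{(n)}}
#' gives
#' \deqn{\left(\frac{d\lambda}{d\tau}\right)^{-1} =
#'   \frac{(2\lambda + A_n)e^{\lambda\tau} + C}{\lambda(C\lambda + D_n)}
#'   - \frac{\tau}{\lambda},}
#' whose real part reduces to the closed form
#' \eqn{(\omega_n^4 + D_n^2 - B_n^2) / ((C\omega_n^2)^2 + (D_n\omega_n)^2)}.
#' When \eqn{Q_n < 0} this is strictly positive, so the conjugate root pair
#' crosses the imaginary axis from left to right with positive speed: each
#' critical delay is a genuine Hopf bifurcation point.
#'
#' @inheritParams hopf_frequencies
#' @param hopf A single Hopf point: one row of [critical_delays()] (or any
#'   list with elements `n`, `omega`, `tau`).
#' @return A list with `dlambda_dtau` (complex derivative of the tracked
#'   root), `re_inverse` (closed-form real part of its reciprocal) and
#'   `sign` (+1). Errors if the crossing is not transversal from the left.
#' @examples
#' hp <- critical_delays(example_params(), 0)
#' transversality(example_params(), hp[1, ])
#' @export
transversality <- function(params, hopf, coupling = c("reduced", "exact")) {
  coupling <- match.arg(coupling)
  mc <- mode_coefficients(params, hopf$n, coupling)
  w <- hopf$omega
  tau <- hopf$tau
  lam <- 1i * w
  den <- lam * (mc$C * lam + mc$D)
  if (Mod(den) < 1e-14) {
    abort("Vanishing denominator in the crossing-speed formula.",
          class = "rdlf_spectral_error")
  }
  inv <- ((2 * lam + mc$A) * exp(lam * tau) + mc$C) / den - tau / lam
  re_closed <- (w^4 + mc$D^2 - mc$B^2) / ((mc$C * w^2)^2 + (mc$D * w)^2)
  if (abs(Re(inv) - re_closed) > 1e-8 * max(1, abs(re_closed))) {
    abort("Internal inconsistency between the crossing-speed expressions.",
          class = "rdlf_spectral_error")
  }
  d <- 1 / inv
  if (Re(d) <= 0) {
    abort("Crossing is not left-to-right: Re(dlambda/dtau) <= 0.",
          class = "rdlf_spectral_error")
  }
  list(dlambda_dtau = d, re_inverse = re_closed, sign = 1)
}

#' Stability of the positive equilibrium at a given delay
#'
#' Classifies the regime of \eqn{E^*}:
#' * `delay_independent_stable` — no spatial mode admits purely imaginary
#'   roots (for the reduced coupling this is \eqn{a_1 > a_2 + bcK/(ar)}), so
#'   \eqn{E^*} is locally asymptotically stable for every delay;
#' * `conditionally_stable` — some modes can destabilize; \eqn{E^*} is
#'   stable for \eqn{\tau < \tau_0} and unstable for \eqn{\tau > \tau_0},
#'   where \eqn{\tau_0} is the smallest critical delay over all modes.
#'
#' At \eqn{\tau = 0} the characteristic equation reduces to
#' \eqn{\lambda^2 + (A_n + C)\lambda + B_n + D_n = 0} with positive
#' coefficients, so by Routh–Hurwitz every mode is stable without delay: in
#' particular diffusion alone cannot destabilize \eqn{E^*} (no Turing
#' instability). This is asserted for all scanned modes.
#'
#' Inputs with \eqn{a_1 < a_2} are accepted but flagged: two candidate
#' frequencies per mode are then possible and the simple
#' stable-below/unstable-above classification need not apply.
#'
#' @inheritParams mode_coefficients
#' @param tau Queried delay (nonnegative).
#' @param n_max Mode-scan bound passed to [mode_cutoff()].
#' @return An object of class `"rdlf_stability"`: a list with `regime`,
#'   `N0`, `tau0`, `tau`, `verdict` (`"stable"`, `"unstable"`, or
#'   `"at_bifurcation"` when within `1e-9` of `tau0`), `hopf_points`
#'   (first-branch critical delays per destabilizing mode, or `NULL`),
#'   `coupling`, and `note`.
#' @examples
#' classify_stability(example_params(), tau = 2)   # stable
#' classify_stability(example_params(), tau = 10)  # unstable
#' @export
classify_stability <- function(params, tau, n_max = 200,
                               coupling = c("reduced", "exact")) {
  coupling <- match.arg(coupling)
  stopifnot(tau >= 0)
  p <- params
  mc <- mode_coefficients(p, 0:n_max, coupling)
  if (any(mc$A + mc$C <= 0) || any(mc$B + mc$D <= 0)) {
    abort("Routh-Hurwitz positivity failed at tau = 0; invalid parameter set.",
          class = "rdlf_spectral_error")
  }
  note <- if (p$a1 < p$a2) "a1 < a2: outside the simply-classified regime" else NA_character_
  N0 <- mode_cutoff(p, n_max, coupling)
  if (is.na(N0)) {
    return(structure(list(regime = "delay_independent_stable", N0 = NA_integer_,
                          tau0 = NA_real_, tau = tau, verdict = "stable",
                          hopf_points = NULL, coupling = coupling, note = note),
                     class = "rdlf_stability"))
  }
  hp <- purrr::map_dfr(0:N0, function(n) critical_delays(p, n, 0, coupling))
  tau0 <- min(hp$tau)
  verdict <- if (tau == 0) {
    "stable"
  } else if (abs(tau - tau0) < 1e-9) {
    "at_bifurcation"
  } else if (tau < tau0) "stable" else "unstable"
  structure(list(regime = "conditionally_stable", N0 = N0, tau0 = tau0,
                 tau = tau, verdict = verdict, hopf_points = hp,
                 coupling = coupling, note = note),
            class = "rdlf_stability")
}

#' @export
print.rdlf_stability <- function(x, ...) {
  cat("Positive equilibrium stability (", x$coupling, " coupling)\n", sep = "")
  cat("  regime : ", x$regime, "\n", sep = "")
  if (!is.na(x$N0)) cat("  N0     : ", x$N0, "\n", sep = "")
  if (!is.na(x$tau0)) cat("  tau0   : ", format(x$tau0), "\n", sep = "")
  cat("  tau    : ", format(x$tau), " -> ", x$verdict, "\n", sep = "")
  if (!is.na(x$note)) cat("  note   : ", x$note, "\n", sep = "")
  invisible(x)
}
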
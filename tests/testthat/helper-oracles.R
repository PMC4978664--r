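# Independent oracles used across the test files. Everything here is kept
# deliberately separate from the package's closed-form implementation paths:
# derivatives are taken by central finite differences, characteristic roots
# are located by grid scan + Newton on the determinant of the linearization
# (not via the package's coefficient formulas), and reference trajectories
# come from deSolve::dede.

# reaction first/second component as plain functions of (N, Nlag, u)
reaction_fn <- function(p) {
  function(N, Nlag, u) {
    c(p$r * N * (1 - (p$a1 * N + p$a2 * Nlag) / p$K - p$c * u),
      p$b * Nlag - p$a * u)
  }
}

# central-difference gradient of component `comp` at state (N, Nlag, u)
fd_gradient <- function(p, comp, at, h = 1e-6) {
  f <- reaction_fn(p)
  vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h
    (f(at[1] + e[1], at[2] + e[2], at[3] + e[3])[comp] -
       f(at[1] - e[1], at[2] - e[2], at[3] - e[3])[comp]) / (2 * h)
  }, numeric(1))
}

# central-difference Hessian of the first component at (N*, N*, u*)
fd_hessian <- function(p, at, h = 1e-4) {
  f <- function(v) reaction_fn(p)(v[1], v[2], v[3])[1]
  H <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    ei <- numeric(3); ei[i] <- h
    ej <- numeric(3); ej[j] <- h
    H[i, j] <- (f(at + ei + ej) - f(at + ei - ej) -
                  f(at - ei + ej) + f(at - ei - ej)) / (4 * h^2)
  }
  H
}

# characteristic function of spatial mode n straight from the linearization
# matrices (bypasses mode_coefficients entirely)
char_det <- function(p, n, lambda, tau, coupling = "reduced") {
  lin <- linearize(p, coupling)
  k2 <- n^2 / p$l^2
  E <- exp(-lambda * tau)
  m11 <- lambda + p$d1 * k2 - lin$J0[1, 1] - lin$J1[1, 1] * E
  m12 <- -lin$J0[1, 2] - lin$J1[1, 2] * E
  m21 <- -lin$J0[2, 1] - lin$J1[2, 1] * E
  m22 <- lambda + p$d2 * k2 - lin$J0[2, 2] - lin$J1[2, 2] * E
  m11 * m22 - m12 * m21
}

# brute-force imaginary-axis crossing: coarse |det| scan over an
# (omega, tau) grid, then 2-D Newton (finite-difference Jacobian) from the
# best grid cells; returns the crossing with smallest tau
oracle_crossing <- function(p, n = 0, coupling = "reduced",
                            omega_max = 3, tau_max = 60) {
  Fv <- function(w, tau) {
    z <- char_det(p, n, 1i * w, tau, coupling)
    c(Re(z), Im(z))
  }
  ws <- seq(0.02, omega_max, length.out = 150)
  ts <- seq(0.05, tau_max, length.out = 300)
  grid <- outer(ws, ts, function(w, t) Mod(char_det(p, n, 1i * w, t, coupling)))
  # take the best 25 grid cells as Newton starts
  ord <- order(grid)[1:25]
  roots <- list()
  for (idx in ord) {
    i <- (idx - 1) %% length(ws) + 1
    j <- (idx - 1) %/% length(ws) + 1
    x <- c(ws[i], ts[j])
    for (it in 1:50) {
      fx <- Fv(x[1], x[2])
      if (max(abs(fx)) < 1e-12) break
      h <- 1e-7
      J <- cbind((Fv(x[1] + h, x[2]) - Fv(x[1] - h, x[2])) / (2 * h),
                 (Fv(x[1], x[2] + h) - Fv(x[1], x[2] - h)) / (2 * h))
      step <- tryCatch(solve(J, fx), error = function(e) NULL)
      if (is.null(step)) break
      x <- x - step
      if (x[1] < 1e-6 || x[2] < 0) break
    }
    if (x[1] > 1e-4 && x[2] > 0 && max(abs(Fv(x[1], x[2]))) < 1e-10) {
      roots[[length(roots) + 1]] <- x
    }
  }
  if (length(roots) == 0) return(NULL)
  m <- do.call(rbind, roots)
  m <- m[order(m[, 2]), , drop = FALSE]
  # smallest tau among found crossings
  c(omega = m[1, 1], tau = m[1, 2])
}

# Newton root-tracking of the characteristic root lambda(tau) near a start
track_root <- function(p, n, tau, lambda0, coupling = "reduced") {
  lam <- lambda0
  for (it in 1:80) {
    f <- char_det(p, n, lam, tau, coupling)
    if (Mod(f) < 1e-14) break
    h <- 1e-8
    df <- (char_det(p, n, lam + h, tau, coupling) -
             char_det(p, n, lam - h, tau, coupling)) / (2 * h)
    lam <- lam - f / df
  }
  lam
}

# random strictly positive parameter set (no regime constraint)
random_params <- function() {
  model_params(
    d1 = runif(1, 0.1, 2), d2 = runif(1, 0.1, 2),
    r = runif(1, 0.2, 1.5), K = runif(1, 0.5, 2),
    a1 = runif(1, 0.5, 4), a2 = runif(1, 0.5, 4),
    c = runif(1, 0.3, 2), b = runif(1, 0.3, 2),
    a = runif(1, 0.3, 2), l = runif(1, 0.5, 3)
  )
}

# random parameter set inside the Hopf regime a2 < a1 < a2 + bcK/(ar)
random_hopf_params <- function() {
  repeat {
    d1 <- runif(1, 0.1, 2); d2 <- runif(1, 0.1, 2)
    r <- runif(1, 0.2, 1.2); K <- runif(1, 0.5, 2)
    a <- runif(1, 0.3, 2); b <- runif(1, 0.3, 2); c <- runif(1, 0.3, 2)
    l <- runif(1, 0.5, 3)
    a2 <- runif(1, 0.5, 3)
    gap <- b * c * K / (a * r)
    a1 <- a2 + runif(1, 0.1, 0.9) * gap
    p <- model_params(d1 = d1, d2 = d2, r = r, K = K, a1 = a1, a2 = a2,
                      c = c, b = b, a = a, l = l)
    if (length(hopf_frequencies(p, 0)) == 1) return(p)
  }
}

# homogeneous reference trajectory via deSolve::dede (constant history)
dede_reference <- function(p, tau, init, times) {
  rhs <- function(t, y, parms) {
    Nlag <- if (t < tau) init[["N"]] else deSolve::lagvalue(t - tau, 1)
    f <- reaction_fn(p)(y[1], Nlag, y[2])
    list(f)
  }
  deSolve::dede(c(init[["N"]], init[["u"]]), times, rhs, NULL,
                atol = 1e-10, rtol = 1e-10)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
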
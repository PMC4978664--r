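p_ref <- example_params()

test_that("mode coefficients reproduce the reference values at n = 0 and 1", {
  mc <- mode_coefficients(p_ref, 0:1)
  expect_equal(mc$A, c(1.24, 1.615))
  expect_equal(mc$B, c(0.24, 0.58125))
  expect_equal(mc$C, c(0.24, 0.24))
  expect_equal(mc$D, c(0.44, 0.5))
  # all strictly positive, C constant across modes
  mc2 <- mode_coefficients(p_ref, 0:20)
  expect_true(all(mc2$A > 0 & mc2$B > 0 & mc2$C > 0 & mc2$D > 0))
  expect_equal(length(unique(mc2$C)), 1L)
})

test_that("without diffusion the coefficients lose their n-dependence", {
  p <- rdlogistic:::validate_params(
    modifyList(unclass(p_ref), list(d1 = 1e-12, d2 = 1e-12)))
  mc <- mode_coefficients(p, c(0, 5, 20))
  expect_lt(max(abs(mc$A - mc$A[1])), 1e-8)
  expect_lt(max(abs(mc$B - mc$B[1])), 1e-8)
  expect_lt(max(abs(mc$D - mc$D[1])), 1e-8)
})

test_that("extinction-state spectrum is explicit and always unstable", {
  sp <- trivial_spectrum(p_ref, 5)
  expect_equal(sp$lambda1[1], 0.6)  # r
  expect_equal(sp$lambda2[1], -1)   # -a
  expect_true(all(diff(sp$lambda1) < 0))
  expect_true(all(diff(sp$lambda2) < 0))
  expect_identical(attr(sp, "verdict"), "unstable")
  withr::with_seed(31, {
    for (i in 1:5) {
      sp <- trivial_spectrum(random_params(), 2)
      expect_gt(sp$lambda1[1], 0) # lambda_{1,0} = r > 0 always
    }
  })
})

test_that("mode-0 Hopf frequency is 0.348266 and mode 1 admits none", {
  om <- hopf_frequencies(p_ref, 0)
  expect_length(om, 1)
  expect_equal(om, 0.348266, tolerance = 1e-5)
  # closed form of the unique root when B^2 - D^2 < 0
  mc <- mode_coefficients(p_ref, 0)
  P <- mc$A^2 - 2 * mc$B - mc$C^2
  Q <- mc$B^2 - mc$D^2
  expect_lt(Q, 0)
  expect_equal(om, sqrt((-P + sqrt(P^2 - 4 * Q)) / 2))
  expect_length(hopf_frequencies(p_ref, 1), 0)
})

test_that("strong instantaneous self-limitation excludes imaginary roots", {
  p <- model_params(d1 = 1, d2 = 0.5, r = 0.6, K = 1, a1 = 5, a2 = 1,
                    c = 1, b = 1, a = 1, l = 2)
  expect_gt(p$a1, p$a2 + p$b * p$c * p$K / (p$a * p$r))
  for (n in 0:50) expect_length(hopf_frequencies(p, n), 0)
  expect_identical(mode_cutoff(p), NA_integer_)
})

test_that("mode cutoff is 0 for the reference set and shrinking l cannot raise it", {
  expect_identical(mode_cutoff(p_ref), 0L)
  # B_n^2 - D_n^2 depends on n only through n^2/l^2, so smaller l can only
  # push modes past the cutoff earlier
  withr::with_seed(58, {
    for (i in 1:10) {
      p <- random_hopf_params()
      n0_big <- mode_cutoff(p)
      p_small <- rdlogistic:::validate_params(
        modifyList(unclass(p), list(l = p$l / 4)))
      n0_small <- mode_cutoff(p_small)
      expect_lte(ifelse(is.na(n0_small), -1L, n0_small),
                 ifelse(is.na(n0_big), -1L, n0_big))
    }
  })
})

test_that("critical delays match the reference table and repeat with 2*pi/omega", {
  cd <- critical_delays(p_ref, 0, j_max = 2)
  expect_rel_equal(cd$tau, c(5.81966, 23.861, 41.9024), 1e-4)
  expect_equal(diff(cd$tau), rep(2 * pi / cd$omega[1], 2), tolerance = 1e-9)
  expect_lt(max(cd$residual), 1e-9)
  # sin(omega tau) > 0 on the principal branch (A D - B C > 0)
  expect_true(all(sin(cd$omega * cd$tau) > 0))
  expect_error(critical_delays(p_ref, 1), "No Hopf",
               class = "rdlf_spectral_error")
})

test_that("the inversion identities cos^2 + sin^2 = 1 and A D - B C > 0 hold", {
  withr::with_seed(77, {
    for (i in 1:20) {
      p <- random_hopf_params()
      mc <- mode_coefficients(p, 0)
      w <- hopf_frequencies(p, 0)
      den <- mc$C^2 * w^2 + mc$D^2
      cosv <- ((mc$D - mc$A * mc$C) * w^2 - mc$B * mc$D) / den
      sinv <- (mc$C * w^3 + (mc$A * mc$D - mc$B * mc$C) * w) / den
      expect_equal(cosv^2 + sinv^2, 1, tolerance = 1e-9)
      expect_gt(mc$A * mc$D - mc$B * mc$C, 0)
    }
  })
})

test_that("characteristic residual behaves as the defining polynomial", {
  mc <- mode_coefficients(p_ref, 0)
  expect_equal(char_residual(p_ref, 0, 0 + 0i, 3), (mc$B + mc$D) + 0i)
  # six-figure rounded inputs leave only rounding-level residual
  expect_lt(Mod(char_residual(p_ref, 0, 0.348266i, 5.81966)), 1e-4)
})

test_that("closed-form crossings coincide with the brute-force root search", {
  # reference set first, then random Hopf-regime draws
  bf <- oracle_crossing(p_ref, 0)
  cd <- critical_delays(p_ref, 0)
  expect_equal(unname(bf["omega"]), cd$omega[1], tolerance = 1e-6)
  expect_equal(unname(bf["tau"]), cd$tau[1], tolerance = 1e-6)
  withr::with_seed(2024, {
    for (i in 1:20) {
      p <- random_hopf_params()
      cd <- critical_delays(p, 0)
      bf <- oracle_crossing(p, 0, tau_max = max(20, 3 * cd$tau[1]),
                            omega_max = max(3, 3 * cd$omega[1]))
      expect_false(is.null(bf))
      expect_rel_equal(unname(bf["omega"]), cd$omega[1], 1e-6)
      expect_rel_equal(unname(bf["tau"]), cd$tau[1], 1e-6)
    }
  })
})

test_that("crossing speed is positive and matches root tracking", {
  cd <- critical_delays(p_ref, 0, j_max = 2)
  signs <- numeric(0)
  for (i in 1:3) {
    tv <- transversality(p_ref, cd[i, ])
    expect_gt(Re(tv$dlambda_dtau), 0)
    signs <- c(signs, sign(Re(tv$dlambda_dtau)))
    # numerical differentiation of the tracked root across the crossing
    h <- 1e-4
    lp <- track_root(p_ref, 0, cd$tau[i] + h, 1i * cd$omega[i])
    lm <- track_root(p_ref, 0, cd$tau[i] - h, 1i * cd$omega[i])
    fd <- (lp - lm) / (2 * h)
    expect_rel_equal(Re(fd), Re(tv$dlambda_dtau), 1e-4)
    expect_rel_equal(Im(fd), Im(tv$dlambda_dtau), 1e-4)
  }
  expect_equal(length(unique(signs)), 1L)
})

test_that("stability classification reproduces the reference phase picture", {
  expect_identical(classify_stability(p_ref, 2)$verdict, "stable")
  expect_identical(classify_stability(p_ref, 10)$verdict, "unstable")
  cls <- classify_stability(p_ref, 2)
  expect_identical(cls$regime, "conditionally_stable")
  expect_identical(cls$N0, 0L)
  expect_equal(cls$tau0, 5.81966, tolerance = 1e-5)
  expect_identical(classify_stability(p_ref, cls$tau0)$verdict,
                   "at_bifurcation")
  # tau = 0 stable for arbitrary valid parameters
  withr::with_seed(5, {
    for (i in 1:5) {
      expect_identical(classify_stability(random_params(), 0)$verdict,
                       "stable")
    }
  })
  # delay-independent regime
  p <- model_params(d1 = 1, d2 = 0.5, r = 0.6, K = 1, a1 = 5, a2 = 1,
                    c = 1, b = 1, a = 1, l = 2)
  cls2 <- classify_stability(p, 50)
  expect_identical(cls2$regime, "delay_independent_stable")
  expect_identical(cls2$verdict, "stable")
  # a1 < a2 inputs are accepted but flagged
  p3 <- model_params(d1 = 1, d2 = 0.5, r = 0.6, K = 1, a1 = 1.5, a2 = 2,
                     c = 1, b = 1, a = 1, l = 2)
  expect_match(classify_stability(p3, 1)$note, "outside")
})
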
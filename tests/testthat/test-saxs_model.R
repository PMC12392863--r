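# UK4-like preset: minimal-linker variant, so the Gaussian-chain term is a
# small (~1%) fraction of the forward intensity
uk4_params <- function() cylinder_params(R = 1.7, eps = 3.3235,
                                         S_cyl = 1, S_pol = 0.01,
                                         Rg = 2, b = 1e-4)

test_q <- function(n = 100) exp(seq(log(0.04), log(3), length.out = n))

test_that("gaussian-chain form factor matches its closed form and limits", {
  expect_equal(debye_chain_ff(0, 2), 1)
  # x = 1: 2/e
  expect_equal(debye_chain_ff(1, 1), 2 * exp(-1), tolerance = 1e-12)
  # large-x asymptote: P * x -> 2
  x <- 50
  expect_equal(debye_chain_ff(sqrt(x), 1) * x, 2 * (x - 1) / x,
               tolerance = 1e-10)
  # monotone decreasing, in [0, 1]
  P <- debye_chain_ff(seq(0, 5, 0.1), 2)
  expect_true(all(P >= 0 & P <= 1))
  expect_true(all(diff(P) <= 0))
})

test_that("guinier limit of the polymer term recovers Rg", {
  Rg <- 2.5
  q <- seq(0.02, 0.3 / Rg, length.out = 20)
  lnI <- log(debye_chain_ff(q, Rg))
  slope <- diff(lnI) / diff(q^2)
  expect_equal(-3 * slope[1], Rg^2, tolerance = 0.01 * Rg^2)
})

test_that("elliptical cylinder form factor is normalized and damped by grading", {
  q <- c(0, test_q(40))
  P <- elliptical_cylinder_ff(q, R = 1.7, eps = 3.3235, L = 100,
                              sigma_surf = 0.5)
  expect_equal(P[1], 1)
  expect_true(all(P >= 0 & P <= 1 + 1e-12))
  # grading damps every q > 0
  P0 <- elliptical_cylinder_ff(test_q(40), 1.7, 3.3235, 100, 0)
  P5 <- elliptical_cylinder_ff(test_q(40), 1.7, 3.3235, 100, 0.5)
  expect_true(all(P5 <= P0 + 1e-15))
  expect_error(elliptical_cylinder_ff(1, -1, 1, 100), "R")
  expect_error(elliptical_cylinder_ff(1, 1, 0.5, 100), "eps")
})

test_that("eps = 1 reduces to the circular cylinder within 1e-6 relative", {
  R <- 1.7; L <- 100
  q <- seq(0.05, 10 / R, length.out = 30)  # q R <= 10
  got <- elliptical_cylinder_ff(q, R, 1, L, 0)
  want <- circular_cylinder_oracle(q, R, L, 0)
  expect_lt(max(abs(got - want) / want), 1e-6)
  # and with the default 0.5 nm grading
  got_g <- elliptical_cylinder_ff(q, R, 1, L, 0.5)
  want_g <- circular_cylinder_oracle(q, R, L, 0.5)
  expect_lt(max(abs(got_g - want_g) / want_g), 1e-6)
})

test_that("model intensity is the scaled sum of its terms", {
  p <- uk4_params()
  q <- test_q(25)
  I <- model_intensity(q, p)
  # componentwise recomputation on random parameter sets
  withr::with_seed(14, {
    for (k in 1:5) {
      pk <- cylinder_params(R = runif(1, 0.5, 4), eps = runif(1, 1, 4),
                            S_cyl = runif(1, 0, 2), S_pol = runif(1, 0, 1),
                            Rg = runif(1, 0.5, 5), b = runif(1, -0.1, 0.1))
      expect_equal(model_intensity(q, pk),
                   pk$S_cyl * elliptical_cylinder_ff(q, pk$R, pk$eps, pk$L,
                                                     pk$sigma_surf) +
                     pk$S_pol * debye_chain_ff(q, pk$Rg) + pk$b,
                   tolerance = 1e-12)
    }
  })
  # q -> 0 limit: S_cyl + S_pol + b
  expect_equal(model_intensity(1e-9, p), p$S_cyl + p$S_pol + p$b,
               tolerance = 1e-6)
  p0 <- cylinder_params(R = 1.7, eps = 2, S_cyl = 0, S_pol = 0, b = 0.37)
  expect_equal(model_intensity(q, p0), rep(0.37, length(q)))
})

test_that("cross-section is reported as full axes", {
  expect_equal(cross_section_report(cylinder_params(R = 1.7, eps = 3.3235)),
               c(minor_nm = 3.4, major_nm = 11.3), tolerance = 1e-4)
  expect_equal(cross_section_report(cylinder_params(R = 3.5, eps = 2.714)),
               c(minor_nm = 7.0, major_nm = 19.0), tolerance = 1e-3)
  cs <- cross_section_report(cylinder_params(R = 2, eps = 1))
  expect_equal(unname(cs[1]), unname(cs[2]))
})

test_that("noise-free curves refit to their generating parameters", {
  truth <- uk4_params()
  curve <- synth_saxs_curve(truth, 0, test_q(60))
  init <- cylinder_params(R = truth$R * 1.3, eps = truth$eps * 1.3,
                          S_cyl = 1.3, S_pol = 0.013, Rg = 2.6, b = 0)
  fit <- fit_cylinder_model(curve, init)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$R - truth$R) / truth$R, 1e-3)
  expect_lt(abs(fit$params$eps - truth$eps) / truth$eps, 1e-3)
  expect_lt(abs(fit$params$Rg - truth$Rg) / truth$Rg, 1e-3)
  expect_lt(abs(fit$params$S_cyl - truth$S_cyl), 1e-3)
  expect_lt(fit$chi2_red, 1e-4)
  expect_equal(fit$n_free, 6)
})

test_that("1% noise gives chi2_red near 1 and a flat-background edge case", {
  truth <- uk4_params()
  curve <- synth_saxs_curve(truth, 0.01, test_q(60), seed = 42)
  init <- cylinder_params(R = 2, eps = 3, S_cyl = 1.2, S_pol = 0.1,
                          Rg = 2.4, b = 0)
  fit <- fit_cylinder_model(curve, init)
  expect_gt(fit$chi2_red, 0.5)
  expect_lt(fit$chi2_red, 2.0)

  flat <- saxs_curve(test_q(30), rep(0.25, 30), rep(0.01, 30))
  ffit <- fit_cylinder_model(flat, cylinder_params(R = 1.5, eps = 2,
                                                   S_cyl = 0.1, S_pol = 0.1,
                                                   b = 0.2))
  expect_lt(ffit$params$S_cyl, 1e-6)
  expect_lt(ffit$params$S_pol, 1e-6)
  expect_equal(ffit$params$b, 0.25, tolerance = 1e-9)
  expect_lt(ffit$chi2, 1e-12)
})

test_that("debye intensity has exact small-system limits", {
  one <- atomic_model("C", 1, "A", 0, 0, 0, f = 3)
  I1 <- atomic_debye_intensity(one, c(0.1, 1, 3))
  expect_equal(I1$I, rep(9, 3))

  d <- 5  # Angstrom
  two <- atomic_model(c("C", "C"), 1:2, "A", c(0, 0), c(0, 0), c(0, d),
                      f = c(1, 1))
  q <- seq(0.5, 30, length.out = 50)  # nm^-1
  I2 <- atomic_debye_intensity(two, q)
  expect_equal(I2$I, 2 * (1 + sin(q * d / 10) / (q * d / 10)),
               tolerance = 1e-12)
  # at q d = pi the cross term vanishes exactly
  q_pi <- pi / (d / 10)
  expect_equal(atomic_debye_intensity(two, q_pi)$I, 2, tolerance = 1e-12)
})

test_that("histogram approximation matches the exact double sum within 0.5%", {
  withr::with_seed(8, {
    model <- atomic_model(
      element = sample(c("C", "N", "O", "S"), 100, replace = TRUE),
      resid = 1:100, chain = "A",
      x = runif(100, 0, 30), y = runif(100, 0, 30), z = runif(100, 0, 30))
  })
  q <- seq(0.1, 5, length.out = 30)
  exact <- atomic_debye_intensity(model, q, method = "exact")
  approx <- atomic_debye_intensity(model, q, method = "histogram")
  expect_lt(max(abs(approx$I - exact$I) / exact$I), 0.005)
})

test_that("hydration layer adds surface scatterers that raise I(0)", {
  withr::with_seed(9, {
    model <- atomic_model("C", 1:20, "A", runif(20, 0, 10),
                          runif(20, 0, 10), runif(20, 0, 10))
  })
  q <- c(0.1, 1)
  dry <- atomic_debye_intensity(model, q)
  wet <- atomic_debye_intensity(model, q,
                                hydration = list(enabled = TRUE))
  expect_gt(wet$I[1], dry$I[1])
})

test_that("assembled fibril scattering shape is length-independent", {
  p <- helical_params(4.8, -2)
  t100 <- synth_helical_trace(p, 100, atoms_per_layer = 8, seed = 6)
  t200 <- synth_helical_trace(p, 200, atoms_per_layer = 8, seed = 6)
  # q window above 2 pi / L for the shorter fibril (L ~ 48 nm)
  q <- seq(0.2, 2, length.out = 25)
  I100 <- atomic_debye_intensity(t100, q, method = "histogram")$I
  I200 <- atomic_debye_intensity(t200, q, method = "histogram")$I
  # per-layer normalized curves agree: doubling the length does not change
  # the cross-section scattering shape
  r <- (I200 / I200[1]) / (I100 / I100[1])
  expect_lt(max(abs(r - 1)), 0.05)
})

test_that("scale/offset fitting is exact and flags degeneracy", {
  q <- test_q(30)
  truth <- uk4_params()
  Im <- model_intensity(q, truth)
  data <- saxs_curve(q, 2.5 * Im + 0.1, sigma = 0.01 * Im + 1e-6)
  res <- fit_scale_offset(saxs_curve(q, Im), data)
  expect_equal(res$scale, 2.5, tolerance = 1e-9)
  expect_equal(res$const, 0.1, tolerance = 1e-9)
  expect_equal(res$chi2_red, 0, tolerance = 1e-12)

  # noisy case: recovered scale within 3 standard errors, and matching lm()
  withr::with_seed(31, {
    noisy <- saxs_curve(q, Im * (1 + rnorm(30, 0, 0.02)),
                        sigma = 0.02 * Im)
  })
  res2 <- fit_scale_offset(saxs_curve(q, Im), noisy)
  expect_lt(abs(res2$scale - 1), 3 * res2$se_scale)
  lmfit <- lm(noisy$I ~ Im, weights = 1 / noisy$sigma^2)
  expect_equal(res2$scale, unname(coef(lmfit)[2]), tolerance = 1e-9)
  expect_equal(res2$const, unname(coef(lmfit)[1]), tolerance = 1e-9)

  const <- saxs_curve(q, rep(1, 30), sigma = rep(0.1, 30))
  expect_error(fit_scale_offset(rep(2, 30), const), "constant")
  expect_error(fit_scale_offset(saxs_curve(q[1:2], Im[1:2]),
                                saxs_curve(q[1:2], Im[1:2],
                                           sigma = rep(1, 2))),
               "3 points")
})

test_that("saxs text files round trip including unit conversion", {
  q <- test_q(20)
  truth <- uk4_params()
  curve <- synth_saxs_curve(truth, 0.01, q, seed = 3)
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# synthetic SAXS curve", "q I sigma",
               sprintf("%.8g %.8g %.8g", curve$q, curve$I, curve$sigma)),
             path)
  back <- read_saxs_curve(path)
  expect_equal(back$q, curve$q, tolerance = 1e-7)
  expect_equal(back$I, curve$I, tolerance = 1e-7)
  expect_equal(back$sigma, curve$sigma, tolerance = 1e-7)
  # Angstrom^-1 input
  writeLines(sprintf("%.8g %.8g %.8g", curve$q / 10, curve$I, curve$sigma),
             path)
  backA <- read_saxs_curve(path, q_unit = "A")
  expect_equal(backA$q, curve$q, tolerance = 1e-7)
})
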
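test_that("closed-form limits of the isotherm hold", {
  # Langmuir: n = 1, omega = 1
  p <- lattice_params(K = 2, omega = 1, n = 1)
  expect_equal(mvh_concentration(0.5, p), 0.5 / (2 * 0.5), tolerance = 1e-12)
  expect_equal(mvh_coverage(0.5, p), 2 * 0.5 / (1 + 2 * 0.5), tolerance = 1e-10)
  expect_equal(mvh_coverage(0, p), 0)

  # initial slope theta/c -> K as theta -> 0, for assorted parameters
  for (pp in list(lattice_params(0.5, 5, 3), lattice_params(0.1, 100, 30),
                  lattice_params(1, 1, 7))) {
    th <- 1e-10
    expect_equal(mvh_concentration(th, pp), th / pp$K, tolerance = 1e-6)
  }
})

test_that("domain errors are raised for invalid densities and parameters", {
  p <- lattice_params(1, 10, 3)
  expect_error(mvh_concentration(1 / 3, p), "1/n")
  expect_error(mvh_concentration(-0.1, p), ">= 0")
  expect_error(lattice_params(-1, 1, 1), "positive")
  expect_error(lattice_params(1, 1, 0), "integer")
})

test_that("concentration/coverage round-trip holds to 1e-9 over 8 decades", {
  for (p in list(lattice_params(0.1, 10, 30), lattice_params(1, 1, 1),
                 lattice_params(0.5, 100, 3))) {
    cgrid <- 10^seq(-4, 4, length.out = 33) / p$K
    th <- mvh_coverage(cgrid, p)
    expect_true(all(th >= 0 & th < 1 / p$n))
    back <- mvh_concentration(th, p)
    expect_lt(max(abs(back - cgrid) / cgrid), 1e-9)
  }
})

test_that("coverage is monotone in c, K and (sub-saturation) omega", {
  p <- lattice_params(0.2, 10, 5)
  cgrid <- 10^seq(-3, 3, length.out = 41)
  th <- mvh_coverage(cgrid, p)
  expect_true(all(diff(th) >= 0))
  th2 <- mvh_coverage(cgrid, lattice_params(0.4, 10, 5))
  expect_true(all(th2 >= th - 1e-12))
  sub <- 5 * th < 0.9
  th3 <- mvh_coverage(cgrid, lattice_params(0.2, 20, 5))
  expect_true(all(th3[sub] >= th[sub] - 1e-12))
})

test_that("the cooperative form is continuous across omega = 1", {
  for (n in c(1, 3, 30)) {
    p0 <- lattice_params(0.3, 1, n)
    cgrid <- 10^seq(-2, 2, length.out = 9)
    for (w in c(1 - 1e-6, 1 + 1e-6)) {
      pw <- lattice_params(0.3, w, n)
      expect_lt(max(abs(mvh_coverage(cgrid, pw) - mvh_coverage(cgrid, p0))),
                1e-6)
    }
  }
})

test_that("finite-lattice oracle matches exhaustive enumeration at M = 4, n = 2", {
  # configurations: empty, 3 single placements, 1 contact pair
  K <- 0.8; w <- 5
  for (cc in c(0.3, 1, 4)) {
    Kc <- K * cc
    Z <- 1 + 3 * Kc + w * Kc^2
    theta <- (3 * Kc + 2 * w * Kc^2) / (4 * Z)
    expect_equal(finite_lattice_coverage(4, cc, lattice_params(K, w, 2)),
                 theta, tolerance = 1e-12)
  }
})

test_that("finite-lattice oracle trivial cases", {
  expect_equal(finite_lattice_coverage(2, 10, lattice_params(1, 5, 3)), 0)
  # single site: Langmuir regardless of omega
  expect_equal(finite_lattice_coverage(1, 2, lattice_params(1, 50, 1)),
               2 / (1 + 2), tolerance = 1e-12)
  expect_equal(finite_lattice_coverage(5, 0, lattice_params(1, 5, 2)), 0)
})

test_that("isotherm inversion agrees with the transfer-matrix oracle", {
  # c at theta = 0.2 for n = 3 via bisection on the oracle, M = 3000
  p <- lattice_params(0.5, 5, 3)
  c_model <- mvh_concentration(0.2, p)
  c_oracle <- uniroot(function(cc) finite_lattice_coverage(3000, cc, p) - 0.2,
                      c(1e-4, 1e3), tol = 1e-10)$root
  expect_lt(abs(c_model - c_oracle) / c_oracle, 0.01)
})

test_that("oracle deviation shrinks with lattice size and is < 1e-2 at M = 3000", {
  p <- lattice_params(1, 10, 3)
  cgrid <- 10^seq(-2, 2, length.out = 7)
  dev <- sapply(c(100, 300, 1000, 3000), function(M)
    max(abs(3 * mvh_coverage(cgrid, p) -
              3 * finite_lattice_coverage(M, cgrid, p))))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[4], 1e-2)
})

test_that("noiseless fits recover the generating parameters on a 3x3 grid", {
  cgrid <- 10^seq(-3.5, 3, length.out = 14)
  for (K in c(0.01, 0.1, 1)) for (w in c(1, 10, 100)) {
    p <- lattice_params(K, w, 30)
    d <- 30 * mvh_coverage(cgrid, p)
    fit <- fit_binding(data.frame(c = cgrid, d = d), n_fixed = 30)
    expect_true(fit$converged)
    expect_lt(abs(fit$K_hat - K) / K, 1e-3)
    expect_lt(abs(fit$omega_hat - w) / w, 1e-3)
  }
})

test_that("fit_binding rejects insufficient or degenerate data", {
  expect_error(fit_binding(data.frame(c = c(1, 2), d = c(0.2, 0.6))),
               "insufficient")
  expect_error(fit_binding(data.frame(c = 1:5, d = rep(0, 5))), "degenerate")
  expect_error(fit_binding(data.frame(c = 1:5, d = rep(1, 5))), "degenerate")
})

test_that("fit_binding honours concentration-axis weights (full ODR path)", {
  p <- lattice_params(0.1, 10, 30)
  cgrid <- 10^seq(-2.5, 1.5, length.out = 12)
  d <- 30 * mvh_coverage(cgrid, p)
  fit <- fit_binding(data.frame(c = cgrid, d = d, weight_d = 1e4,
                                weight_c = 1e4), n_fixed = 30)
  expect_true(fit$converged)
  expect_lt(abs(fit$K_hat - 0.1) / 0.1, 1e-3)
  expect_lt(abs(fit$omega_hat - 10) / 10, 1e-3)
})

test_that("mvh_fit methods are coherent", {
  p <- lattice_params(0.1, 10, 30)
  cgrid <- 10^seq(-2.5, 1.5, length.out = 12)
  set.seed(1)
  d <- 30 * mvh_coverage(cgrid, p) + rnorm(12, 0, 0.02)
  fit <- fit_binding(data.frame(c = cgrid, d = d, sd_d = 0.02), n_fixed = 30)
  expect_named(coef(fit), c("K", "omega"))
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  expect_equal(length(residuals(fit)), 12L)
  expect_equal(predict(fit, cgrid), fit$points$d_fit, tolerance = 1e-10)
  sims <- simulate(fit, nsim = 3, seed = 7)
  expect_equal(dim(sims), c(12L, 3L))
  expect_output(print(summary(fit)), "McGhee-von Hippel")
  tf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  write_fit_json(fit, tf, curve_path = cf)
  rep <- jsonlite::read_json(tf)
  expect_equal(rep$K, fit$K_hat, tolerance = 1e-12)
  expect_equal(nrow(read.csv(cf)), 100L)
})
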
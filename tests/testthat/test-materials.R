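test_that("uniaxial nominal stress matches numerical differentiation of the
           strain-energy function", {
  W <- function(lam, cf) {
    i1 <- lam^2 + 2 / lam
    sum(cf * (i1 - 3)^seq_along(cf))
  }
  for (cf in list(0.5, c(0.3, 1.0), c(0.2, 0.8, 2.5))) {
    m <- reduced_polynomial_model(cf)
    for (lam in c(1.01, 1.05, 1.1, 1.3)) {
      h <- 1e-6
      dW <- (W(lam + h, cf) - W(lam - h, cf)) / (2 * h)
      P <- uniaxial_nominal_stress(m, lam - 1)
      expect_lt(abs(P - dW) / max(abs(dW), 1e-12), 1e-8)
    }
  }
})

test_that("neo-Hookean closed form and the small-strain limit E = 6 C10
           hold", {
  C10 <- 0.5
  m <- reduced_polynomial_model(C10, "ON")
  lam <- 1.1
  expect_equal(uniaxial_nominal_stress(m, 0.1),
               2 * C10 * (lam - lam^-2), tolerance = 1e-12)
  expect_equal(uniaxial_nominal_stress(m, 0), 0)
  h <- 1e-7
  slope0 <- uniaxial_nominal_stress(m, h) / h
  expect_equal(slope0, 6 * C10, tolerance = 1e-5)
  expect_error(uniaxial_nominal_stress(m, -1.5), "exceed -1")
  expect_error(reduced_polynomial_model(c(-0.1, 1)), "positive")
  expect_error(reduced_polynomial_model(rep(0.1, 4)), "order")
})

test_that("reduced-polynomial fitting recovers known coefficients", {
  m_true <- reduced_polynomial_model(c(0.3, 1.0), "peripapillary")
  eps <- seq(0.005, 0.1, length.out = 60)
  cur <- stress_strain_curve(eps, uniaxial_nominal_stress(m_true, eps),
                             "peripapillary")
  m_fit <- fit_reduced_polynomial(cur, order = 2)
  expect_lt(max(abs(m_fit$coefficients - c(0.3, 1.0))), 1e-6)
  expect_gt(attr(m_fit, "r_squared"), 1 - 1e-10)
  # fit -> predict round-trip is the identity on model-generated data
  expect_equal(uniaxial_nominal_stress(m_fit, eps),
               cur$stress, tolerance = 1e-8)
  # linear small-strain data at order 1: C10 = E / 6
  E <- 3
  lin <- stress_strain_curve(seq(1e-4, 5e-3, length.out = 40),
                             E * seq(1e-4, 5e-3, length.out = 40), "ON")
  m1 <- fit_reduced_polynomial(lin, order = 1)
  expect_equal(m1$coefficients, E / 6, tolerance = 0.01)
})

test_that("coefficient recovery is unbiased to within 5% median error at 2%
           stress noise", {
  m_true <- reduced_polynomial_model(c(0.3, 1.0))
  eps <- seq(0.005, 0.1, length.out = 60)
  sig0 <- uniaxial_nominal_stress(m_true, eps)
  err <- vapply(1:50, function(s) {
    set.seed(s + 400)
    f <- fit_reduced_polynomial(
      stress_strain_curve(eps, sig0 * (1 + rnorm(60, 0, 0.02))), order = 2)
    (f$coefficients - c(0.3, 1.0)) / c(0.3, 1.0)
  }, c(0, 0))
  # bias = systematic (median signed) relative deviation per coefficient
  expect_lt(max(abs(apply(err, 1, median))), 0.05)
})

test_that("pre-stretch translates the strain axis, is additive, and leaves
           stress untouched", {
  cur <- synth_tensile(noise_sigma = 0, seed = 1)
  same <- apply_prestretch(cur, prestretch_spec(0))
  expect_equal(same$strain, cur$strain)
  shifted <- apply_prestretch(cur, prestretch_spec(0.05))
  expect_equal(shifted$strain, cur$strain + 0.05, tolerance = 1e-15)
  expect_equal(shifted$stress, cur$stress)
  twice <- apply_prestretch(apply_prestretch(cur, prestretch_spec(0.025)),
                            prestretch_spec(0.025))
  expect_equal(twice$strain, shifted$strain, tolerance = 1e-15)
  expect_error(prestretch_spec(-0.01))
})

test_that("the lamina cribrosa curve is the pointwise ON/PPS average and is
           bounded by its inputs", {
  eps <- seq(0.001, 0.1, length.out = 50)
  on <- stress_strain_curve(eps, 2 * eps, "ON")
  pps <- stress_strain_curve(eps, 4 * eps, "peripapillary")
  lc <- lamina_curve(on, pps)
  expect_equal(lc$stress, 3 * lc$strain, tolerance = 1e-9)
  expect_equal(lc$region, "lamina_cribrosa")
  same <- lamina_curve(on, on)
  expect_equal(same$stress, 2 * same$strain, tolerance = 1e-9)
  # realistic curved inputs: output between the inputs pointwise
  on2 <- synth_tensile("ON", 1.3, 1.3, 0.03, 0.02, 0, seed = 1)
  pps2 <- synth_tensile("peripapillary", 1.6, 1.6, 0.03, 0.08, 0, seed = 2)
  lc2 <- lamina_curve(on2, pps2)
  lo <- pmin(approx(on2$strain, on2$stress, lc2$strain)$y,
             approx(pps2$strain, pps2$stress, lc2$strain)$y)
  hi <- pmax(approx(on2$strain, on2$stress, lc2$strain)$y,
             approx(pps2$strain, pps2$stress, lc2$strain)$y)
  expect_true(all(lc2$stress >= lo - 1e-12 & lc2$stress <= hi + 1e-12))
  disjoint <- stress_strain_curve(eps + 1, 2 * eps, "ON")
  expect_error(lamina_curve(on, disjoint), "overlap")
})

test_that("material models serialize to JSON and a tabulated card", {
  m <- reduced_polynomial_model(c(0.3, 1.0), "posterior")
  attr(m, "r_squared") <- 0.999
  jf <- tempfile(fileext = ".json")
  write_material_json(m, jf)
  j <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(as.numeric(j$coefficients), c(0.3, 1.0))
  expect_equal(j$poisson, 0.495)
  cf <- tempfile(fileext = ".txt")
  write_material_card(m, cf)
  lines <- readLines(cf)
  expect_true(any(grepl("strain,stress_mpa", lines)))
  tab <- read.csv(cf, skip = 4)
  expect_equal(tab$stress_mpa,
               uniaxial_nominal_stress(m, tab$strain), tolerance = 1e-6)
})
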
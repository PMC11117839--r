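test_that("stress-strain conversion is exact for a constant-stiffness
           record and scale-consistent in the cross-section", {
  k <- 0.8  # N/mm
  L0 <- 8; w <- 2; t <- 0.5
  len <- seq(L0 * 0.99, L0 * 1.1, length.out = 80)
  force <- pmax(k * (len - L0 * 0.99), 0)
  rec <- tensile_record(force, len, w, t, "posterior", preload = 0.02)
  cur <- to_stress_strain(rec)
  # slope of stress vs strain = k * L0' / (w t) with L0' the preload length
  i0 <- which(force >= 0.02)[1]
  L0p <- len[i0]
  fit <- stats::lm(cur$stress ~ cur$strain)
  expect_equal(unname(stats::coef(fit)[2]), k * L0p / (w * t),
               tolerance = 1e-6)
  expect_equal(cur$stress[1], 0.02 / (w * t), tolerance = 0.02)
  # doubling the width halves the stress exactly
  rec2 <- tensile_record(force, len, 2 * w, t, "posterior", preload = 0.02)
  cur2 <- to_stress_strain(rec2)
  expect_equal(cur2$stress, cur$stress / 2, tolerance = 1e-12)
  expect_error(to_stress_strain(tensile_record(force, len, 0.0, t)))
})

test_that("rupture truncation drops post-peak samples", {
  len <- seq(8, 9, length.out = 50)
  force <- c(seq(0.02, 2, length.out = 40), seq(1.8, 0.5, length.out = 10))
  rec <- tensile_record(force, len, 2, 0.5, "ON")
  cur <- to_stress_strain(rec)
  expect_equal(length(cur$stress), 40)
  expect_equal(which.max(cur$stress), length(cur$stress))
  expect_false(is.na(cur$truncation))
})

test_that("synthetic records round-trip through the stress-strain
           conversion", {
  cur0 <- synth_tensile(noise_sigma = 0, seed = 2)
  rec <- synth_tensile_record(cur0, width = 2.11, thickness = 0.5)
  cur <- to_stress_strain(rec)
  # reconstructed stress carries the preload offset; strains line up
  expect_equal(cur$strain[-1], cur0$strain, tolerance = 1e-9)
  expect_equal(cur$stress[-1] - rec$preload / (2.11 * 0.5), cur0$stress,
               tolerance = 1e-9)
})

test_that("tangent moduli are exact on polynomial data and analytic for a
           quadratic", {
  eps <- seq(0.002, 0.1, length.out = 70)
  lin <- stress_strain_curve(eps, 1 + 10 * eps, "anterior")
  tm <- fit_tangent_moduli(lin, c(0.03, 0.06))
  expect_equal(tm$modulus_mpa, c(10, 10), tolerance = 1e-7)
  A <- 5
  quad <- stress_strain_curve(eps, A * eps^2, "ON_sheath")
  tm2 <- fit_tangent_moduli(quad, c(0.03, 0.07))
  expect_equal(tm2$modulus_mpa, 2 * A * c(0.03, 0.07), tolerance = 1e-8)
  # quintic exactness at the top of the order range
  cf <- c(0.1, 2, -3, 40, -100, 800)
  quint <- stress_strain_curve(eps, vapply(eps, function(e)
    sum(cf * e^(0:5)), 0), "equatorial")
  tm3 <- fit_tangent_moduli(quint, c(0.03, 0.06), order = 5)
  oracle <- vapply(c(0.03, 0.06), function(e)
    sum(cf[-1] * (1:5) * e^(0:4)), 0)
  expect_equal(tm3$modulus_mpa, oracle, tolerance = 1e-6)
  # out-of-range strain points are flagged
  tm4 <- fit_tangent_moduli(lin, c(0.03, 0.5))
  expect_true(is.na(tm4$modulus_mpa[2]) && !tm4$in_range[2])
})

test_that("sheath-like curves stiffen: modulus at 7% exceeds modulus at 3%",
{
  cur <- synth_tensile(noise_sigma = 0.02, seed = 5)
  tm <- fit_tangent_moduli(cur, c(0.03, 0.07))
  expect_gt(tm$modulus_mpa[2], tm$modulus_mpa[1])
})

test_that("bilinear log-log regression recovers noiseless breakpoints
           exactly and is globally optimal over its search set", {
  cur <- synth_tensile(noise_sigma = 0, seed = 1)
  gt <- attr(cur, "ground_truth")
  fit <- bilinear_loglog(cur)
  expect_false(fit$degenerate)
  expect_equal(fit$transition_strain, gt$breakpoint_strain,
               tolerance = 1e-9)
  expect_equal(fit$slope_low, gt$gamma_low, tolerance = 1e-9)
  expect_equal(fit$slope_high, gt$gamma_high, tolerance = 1e-9)
  expect_gt(fit$r2_low, 0.999); expect_gt(fit$r2_high, 0.999)
  expect_true(all(fit$sse_total <= fit$sse_by_break + 1e-15))
  # high-contrast exponent pair, exact recovery as well
  cur2 <- synth_tensile(gamma_low = 1.2, gamma_high = 2.5,
                        noise_sigma = 0, seed = 1)
  fit2 <- bilinear_loglog(cur2)
  expect_equal(fit2$transition_strain, 0.034, tolerance = 1e-9)
  expect_equal(fit2$slope_high, 2.5, tolerance = 1e-9)
})

test_that("breakpoint recovery holds across seeds at 2% stress noise", {
  errs <- vapply(1:20, function(s)
    bilinear_loglog(synth_tensile(seed = s))$transition_strain - 0.034, 0)
  expect_lt(max(abs(errs)), 0.004)
})

test_that("a single power law is flagged degenerate and unit changes leave
           the fit invariant", {
  cur <- synth_tensile(gamma_low = 1.5, gamma_high = 1.5, noise_sigma = 0)
  fit <- bilinear_loglog(cur)
  expect_true(fit$degenerate)
  expect_equal(fit$slope_low, fit$slope_high, tolerance = 0.05)
  # stress rescaling (MPa -> kPa) shifts intercepts only
  cur2 <- synth_tensile(noise_sigma = 0.02, seed = 3)
  f1 <- bilinear_loglog(cur2)
  cur3 <- cur2; cur3$stress <- cur2$stress * 1000
  f2 <- bilinear_loglog(cur3)
  expect_equal(f2$transition_strain, f1$transition_strain,
               tolerance = 1e-12)
  expect_equal(f2$slope_low, f1$slope_low, tolerance = 1e-12)
  expect_error(bilinear_loglog(stress_strain_curve(1:5 / 100, 1:5)),
               "at least 8")
})

test_that("tensile CSV + YAML sidecar I/O reconstructs the record", {
  cur0 <- synth_tensile(noise_sigma = 0, seed = 2)
  rec <- synth_tensile_record(cur0)
  csv <- tempfile(fileext = ".csv"); yml <- tempfile(fileext = ".yaml")
  write.csv(data.frame(time_s = seq_along(rec$force) / 5,
                       force_N = rec$force, length_mm = rec$grip_length),
            csv, row.names = FALSE)
  yaml::write_yaml(list(width_mm = rec$width, thickness_mm = rec$thickness,
                        region = rec$region, preload_N = rec$preload), yml)
  back <- read_tensile_csv(csv, yml)
  expect_equal(back$force, rec$force, tolerance = 1e-9)
  expect_equal(back$width, rec$width)
  expect_equal(back$region, rec$region)
})
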
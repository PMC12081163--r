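test_that("Mie efficiency approaches the Rayleigh limit for small spheres", {
  m <- 1.587 / 1.332
  x <- 0.05
  q <- mie_efficiencies(m, x)
  rayleigh <- (8 / 3) * x^4 * ((m^2 - 1) / (m^2 + 2))^2
  expect_equal(q$Qsca, rayleigh, tolerance = 1e-3)
})

test_that("scattering coefficient is additive and linear in concentration", {
  s1 <- suspension_spec(5, 0.04)
  s2 <- suspension_spec(1, 0.001)
  s12 <- suspension_spec(c(5, 1), c(0.04, 0.001))
  r <- mie_mu_s(s12)
  expect_equal(r$total, mie_mu_s(s1)$total + mie_mu_s(s2)$total,
               tolerance = 1e-10)
  expect_equal(r$total, sum(r$per_component$mu_s_cm), tolerance = 1e-10)
  expect_equal(mie_mu_s(suspension_spec(5, 0.08))$total,
               2 * mie_mu_s(s1)$total, tolerance = 1e-10)
})

test_that("suspension_spec validates input", {
  expect_error(suspension_spec(c(5, 1), 0.04), "length")
  expect_error(suspension_spec(-5, 0.04))
  expect_error(suspension_spec(5, 1.5))
})

test_that("phantom parameters enforce their domain", {
  expect_error(phantom_params(xi_A = 40, xi_L = 12), "xi")
  expect_error(phantom_params(rot_rate = 10))
  expect_error(phantom_params(rot_jitter = -1))
  p <- phantom_params()
  expect_true(p$xi_A < p$xi_L && p$xi_L < p$xi_C)
})

test_that("the layered forward model is physical and normalized on 2-20 mm", {
  for (d in seq(2, 20, by = 1.5)) {
    M <- layered_mueller(d)
    expect_equal(M[1, 1], 1, tolerance = 1e-12)
    expect_true(is_physical(M, tol = 1e-9))
  }
})

test_that("the noiseless model has the designed feature trends", {
  depths <- seq(2, 20, 2)
  f <- do.call(rbind, lapply(depths, function(d) {
    as.data.frame(features_from_mueller(layered_mueller(d), n_states = 500))
  }))
  expect_true(all(diff(f$Kc) < 0))
  expect_true(all(diff(f$t1) < 0))
  expect_true(all(diff(f$Ct) > 0))
  expect_true(all(diff(f$CtDelta) > 0))
  expect_true(all(diff(f$RV) > 0))
  expect_true(all(diff(f$RVD) > 0))
  expect_gt(abs(pcc(f$Delta, rep(depths, 1))), 0.9)
})

test_that("an infinitely deep layer reduces to the rotated background", {
  p <- phantom_params()
  M <- layered_mueller(1e6, p)
  expect_equal(kc(M), p$bg_circular, tolerance = 1e-6)
})

test_that("generate_depth_sweep returns complete, reproducible records", {
  p <- phantom_params()
  sw <- generate_depth_sweep(p, depths = c(2, 6, 10), grid = c(3, 3),
                             repeats = 2, seed = 123, n_states = 200)
  expect_s3_class(sw, "depth_sweep")
  rec <- sw$records
  expect_equal(nrow(rec), 3 * 9 * 2)
  expect_true(all(c("depth", "cell_row", "cell_col", "repeat_id",
                    "Kc", "t1", "Ct", "CtDelta", "RV", "RVD", "flag") %in%
                    names(rec)))
  expect_true(all(table(rec$depth) == 18))
  sw2 <- generate_depth_sweep(p, depths = c(2, 6, 10), grid = c(3, 3),
                              repeats = 2, seed = 123, n_states = 200)
  expect_identical(rec$Kc, sw2$records$Kc)
  mu <- tapply(rec$Kc, rec$depth, mean)
  expect_true(all(diff(mu) < 0))
})

test_that("measurement noise perturbs features without breaking extraction", {
  p <- phantom_params(noise_level = 0.02)
  sw <- generate_depth_sweep(p, depths = c(4, 12), grid = c(2, 2),
                             repeats = 2, seed = 5, n_states = 200)
  p0 <- phantom_params(noise = "none", rot_jitter = 0)
  sw0 <- generate_depth_sweep(p0, depths = c(4, 12), grid = c(2, 2),
                              repeats = 2, seed = 5, n_states = 200)
  expect_false(isTRUE(all.equal(sw$records$Kc, sw0$records$Kc)))
  expect_true(all(is.finite(sw$records$Ct)))
  expect_true(all(!sw$records$flag))
})
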
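test_that("polar decomposition recovers pure-element parameters", {
  p <- mmpd(mm_linear_retarder(70, 25))
  expect_equal(p$delta, 70, tolerance = 1e-8)
  expect_equal(p$D, 0, tolerance = 1e-10)
  expect_equal(p$Delta, 0, tolerance = 1e-10)
  d <- mmpd(mm_linear_diattenuator(0.4, -30))
  expect_equal(d$D, 0.4, tolerance = 1e-10)
  expect_equal(d$Delta, 0, tolerance = 1e-8)
  r <- mmpd(mm_rotator(10))
  expect_equal(r$psi, 10, tolerance = 1e-8)
  expect_equal(r$delta, 0, tolerance = 1e-6)
})

test_that("polar decomposition factors a composite in the canonical order", {
  Md <- mm_depolarizer(0.7, 0.6, 0.5)
  Mr <- mm_linear_retarder(40, 15)
  Mq <- mm_linear_diattenuator(0.3, 30)
  p <- mmpd(Md %*% Mr %*% Mq)
  expect_equal(p$D, 0.3, tolerance = 1e-8)
  expect_equal(p$Delta, 1 - mean(c(0.7, 0.6, 0.5)), tolerance = 1e-8)
  expect_equal(p$delta, 40, tolerance = 1e-6)
  expect_mueller_equal(p$M_Delta %*% p$M_R %*% p$M_D, Md %*% Mr %*% Mq, 1e-8)
})

test_that("polar factors multiply back to the input on random matrices", {
  set.seed(11)
  for (i in 1:20) {
    M <- random_physical_mueller()
    p <- mmpd(M)
    expect_mueller_equal(p$M_Delta %*% p$M_R %*% p$M_D, M, 1e-7)
  }
})

test_that("Cloude decomposition has the textbook limits", {
  cid <- mmcd(diag(4))
  expect_equal(cid$P1, 1, tolerance = 1e-10)
  expect_equal(cid$S, 0, tolerance = 1e-10)
  cdep <- mmcd(diag(c(1, 0, 0, 0)))
  expect_equal(cdep$lambda, rep(0.25, 4), tolerance = 1e-10)
  expect_equal(cdep$S, 1, tolerance = 1e-10)    # entropy log base 4
  expect_equal(cdep$PDelta, 0, tolerance = 1e-10)
  set.seed(12)
  for (i in 1:10) {
    cc <- mmcd(random_physical_mueller())
    expect_true(all(diff(cc$lambda) <= 1e-12))  # sorted decreasing
    expect_equal(sum(cc$lambda), 1, tolerance = 1e-8)
  }
})

test_that("Cloude decomposition tolerance handles near-physical input", {
  M <- diag(c(1, 1, 1, -1))           # grossly unphysical
  expect_error(mmcd(M), "unphysical")
  N <- diag(c(1, 0.5, 0.5, 0.5 - 0.04))
  N[4, 4] <- -0.02                    # mildly unphysical perturbation
  expect_silent(mmcd(N, tol = 0.05))
})

test_that("anisotropy parameters match closed forms for a pure retarder", {
  t <- mmt(mm_linear_retarder(40, 0))
  expect_equal(t$t1, 0.5 * (1 - cos(40 * pi / 180)), tolerance = 1e-10)
  expect_equal(t$b, 0.5 * (1 + cos(40 * pi / 180)), tolerance = 1e-10)
})

test_that("t1 is invariant under an output-side rotator", {
  set.seed(13)
  for (i in 1:10) {
    M <- random_physical_mueller()
    phi <- runif(1, -90, 90)
    expect_equal(mmt(mm_rotator(phi) %*% M)$t1, mmt(M)$t1, tolerance = 1e-10)
  }
})

test_that("rotation-invariant parameters read pure elements correctly", {
  r <- rip(mm_linear_diattenuator(0.4, -30))
  expect_equal(r$DL, 0.4, tolerance = 1e-10)
  expect_equal(r$DC, 0, tolerance = 1e-10)
  expect_equal(r$PL, 0.4, tolerance = 1e-10)
  set.seed(14)
  M <- random_physical_mueller()
  a <- rip(M); b <- rip(rotate_frame(M, 37))
  for (nm in c("PL", "DL", "qL", "rL")) {
    expect_equal(a[[nm]], b[[nm]], tolerance = 1e-8)
  }
})

test_that("sphere mapping of the identity is the unit sphere", {
  g <- gpse(diag(4), n_states = 2000)
  expect_equal(g$V, 1, tolerance = 1e-6)
  expect_equal(g$E, 0, tolerance = 1e-6)
  expect_equal(g$Dstar, 0, tolerance = 1e-8)
  expect_equal(g$RA, 0, tolerance = 1e-6)
})

test_that("sphere mapping recovers diagonal depolarizer semi-axes", {
  g <- gpse(mm_depolarizer(0.8, 0.6, 0.4), n_states = 2000)
  expect_equal(sort(c(g$a, g$b, g$c), decreasing = TRUE), c(0.8, 0.6, 0.4),
               tolerance = 1e-6)
  expect_equal(g$V, (0.8 * 0.6 * 0.4)^(1 / 3), tolerance = 1e-6)
})

test_that("a rotator drives alignment without shrinking the sphere", {
  g <- gpse(mm_rotator(30), n_states = 2000)
  expect_equal(g$V, 1, tolerance = 1e-6)
  expect_gt(g$RA, 0.1)
})

test_that("sphere statistics are invariant under an output-side rotator", {
  set.seed(15)
  M <- random_physical_mueller()
  a <- gpse(M, n_states = 4000)
  b <- gpse(mm_rotator(25) %*% M, n_states = 4000)
  expect_equal(a$V, b$V, tolerance = 1e-8)
  expect_equal(a$Dstar, b$Dstar, tolerance = 1e-8)
})
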
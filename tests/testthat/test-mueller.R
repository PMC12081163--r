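test_that("normalize_mueller scales by m11 and is idempotent", {
  M <- diag(c(2, 1, 1, 1))
  N <- normalize_mueller(M)
  expect_equal(N[1, 1], 1)
  expect_equal(N, normalize_mueller(N))
  expect_error(normalize_mueller(diag(c(-1, 1, 1, 1))), "m11")
  expect_warning(normalize_mueller(matrix(c(1, 0, 0, 0,
                                            2, 1, 0, 0,
                                            0, 0, 1, 0,
                                            0, 0, 0, 1), 4, 4)), "passive")
})

test_that("shape checks reject malformed input", {
  expect_error(normalize_mueller(diag(3)), "4 x 4")
  expect_error(normalize_mueller(matrix(letters[1:16], 4, 4)), "numeric")
  M <- diag(4); M[2, 2] <- NA
  expect_error(normalize_mueller(M), "non-finite")
})

test_that("coherency matrix of identity is rank one with eigenvalue 1", {
  ev <- coherency_eigenvalues(diag(4))
  expect_equal(ev, c(1, 0, 0, 0), tolerance = 1e-12)
})

test_that("coherency eigenvalues of the ideal depolarizer are uniform", {
  ev <- coherency_eigenvalues(diag(c(1, 0, 0, 0)))
  expect_equal(ev, rep(0.25, 4), tolerance = 1e-12)
})

test_that("trace of the coherency matrix equals m11", {
  set.seed(1)
  for (i in 1:20) {
    M <- random_physical_mueller()
    expect_equal(sum(coherency_eigenvalues(M)), M[1, 1], tolerance = 1e-10)
  }
})

test_that("is_physical accepts physical and rejects unphysical matrices", {
  expect_true(is_physical(diag(4)))
  expect_true(is_physical(mm_linear_retarder(65, 30)))
  bad <- diag(c(1, 1, 1, -1))
  expect_false(is_physical(bad))
  expect_lt(attr(is_physical(bad), "min_eigenvalue"), 0)
  set.seed(2)
  for (i in 1:20) expect_true(is_physical(random_physical_mueller()))
})

test_that("rotation matrices compose and invert", {
  expect_mueller_equal(mm_rotation(30) %*% mm_rotation(-30), diag(4), 1e-12)
  expect_mueller_equal(mm_rotation(20) %*% mm_rotation(25), mm_rotation(45),
                       1e-12)
  # full turn of the frame is 180 degrees (double-angle convention)
  expect_mueller_equal(mm_rotation(180), diag(4), 1e-12)
})

test_that("rotate_frame preserves m11, m44 and physical realizability", {
  set.seed(3)
  for (i in 1:10) {
    M <- random_physical_mueller()
    R <- rotate_frame(M, runif(1, -180, 180))
    expect_equal(R[1, 1], M[1, 1], tolerance = 1e-12)
    expect_equal(R[4, 4], M[4, 4], tolerance = 1e-12)
    expect_true(is_physical(R, tol = 1e-8))
  }
})

test_that("quarter-wave plate at axis 0 has the documented form", {
  Q <- mm_linear_retarder(90, 0)
  expect_mueller_equal(Q, matrix(c(1, 0, 0, 0,
                                   0, 1, 0, 0,
                                   0, 0, 0, 1,
                                   0, 0, -1, 0), 4, 4, byrow = TRUE), 1e-12)
  # QWP at 0 maps +S2 to -S3
  expect_equal(as.numeric(Q %*% c(1, 0, 1, 0)), c(1, 0, 0, -1),
               tolerance = 1e-12)
})

test_that("elementary elements are physical and normalized", {
  expect_true(is_physical(mm_linear_retarder(137, 12)))
  expect_true(is_physical(mm_linear_diattenuator(0.7, -40)))
  expect_true(is_physical(mm_depolarizer(0.5, 0.4, 0.3)))
  expect_true(is_physical(mm_rotator(33)))
  expect_equal(mm_linear_diattenuator(0, 10), diag(4))
  expect_error(mm_linear_diattenuator(1.2), "q")
  expect_error(mm_depolarizer(2), "\\[-1, 1\\]")
})

test_that("half-wave retarder flips the sign of the 45-degree component", {
  H <- mm_linear_retarder(180, 0)
  expect_equal(as.numeric(H %*% c(1, 0, 1, 0)), c(1, 0, -1, 0),
               tolerance = 1e-12)
})

test_that("stokes_dop computes the degree of polarization", {
  expect_equal(stokes_dop(c(1, 1, 0, 0)), 1)
  expect_equal(stokes_dop(c(2, 1, 0, 0)), 0.5)
  expect_equal(stokes_dop(c(1, 0, 0, 0)), 0)
  expect_error(stokes_dop(c(0, 1, 0, 0)), "S0")
})
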
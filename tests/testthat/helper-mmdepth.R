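# Shared helpers for the test suite.

# Random physical Mueller matrix: product of elementary elements with a
# diagonal depolarizer, optionally convexly mixed with a second product.
# Products and convex combinations of physical matrices are physical.
random_physical_mueller <- function(mix = TRUE) {
  one <- function() {
    M <- mm_linear_diattenuator(runif(1, 0, 0.6), runif(1, -90, 90)) %*%
      mm_linear_retarder(runif(1, 0, 180), runif(1, -90, 90)) %*%
      mm_depolarizer(runif(1, 0.3, 1))
    rotate_frame(M, runif(1, -90, 90))
  }
  M <- one()
  if (mix && runif(1) < 0.5) {
    w <- runif(1)
    M <- w * M + (1 - w) * one()
  }
  normalize_mueller(M, warn = FALSE)
}

expect_mueller_equal <- function(A, B, tol = 1e-8) {
  expect_lt(max(abs(A - B)), tol)
}
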
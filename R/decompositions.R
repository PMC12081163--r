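#' Polarization basic parameter (PBP) systems
#'
#' Five standard parameter systems are derived from an m11-normalized
#' Mueller matrix:
#'
#' * **MMPD** (Lu-Chipman polar decomposition): `M = M_Delta M_R M_D`,
#'   yielding diattenuation `D`, depolarization `Delta`, linear retardance
#'   `delta` and circular retardance `psi`.
#' * **MMCD** (Cloude coherency decomposition): eigenvalues of the
#'   coherency matrix yield purity indices `P1, P2, P3`, overall purity
#'   `PI`, depolarization index `PDelta` and polarization entropy `S`.
#' * **MMT** (Mueller matrix transformation): direct element combinations
#'   `t1, t2, t3, b, A`.
#' * **RIP** (rotation-invariant parameters): `PL, PC, DL, DC, qL, rL`.
#' * **GPSE** (global-polarization Stokes ellipsoid): the ellipsoid traced
#'   on the Poincare sphere by the images of all fully polarized states,
#'   yielding semi-axes `a >= b >= c`, center, volume-equivalent radius `V`,
#'   eccentricity `E`, center-offset anisotropy `Dstar`, and the
#'   phase-delay statistics `RA, RD, RS`.
#'
#' @name pbp
NULL

pinv3 <- function(A, tol = 1e-12) {
  s <- svd(A)
  d <- ifelse(s$d > tol * max(s$d, tol), 1 / s$d, 0)
  s$v %*% (d * t(s$u))
}

#' Lu-Chipman polar decomposition (MMPD)
#'
#' Factors a normalized Mueller matrix as
#' `M = M_Delta %*% M_R %*% M_D` (depolarizer, retarder, diattenuator) and
#' derives
#' `D = sqrt(m12^2 + m13^2 + m14^2)`,
#' `Delta = 1 - |tr(M_Delta) - 1| / 3`,
#' `delta = acos(sqrt((M_R[2,2] + M_R[3,3])^2 + (M_R[3,2] - M_R[2,3])^2) - 1)`,
#' and the circular retardance
#' `psi = 0.5 * atan2(M_R[3,2] - M_R[2,3], M_R[2,2] + M_R[3,3])`
#' (the rotator form with the `+` denominator; see the package vignette for
#' the sign conventions).
#'
#' @param M m11-normalized Mueller matrix.
#' @return list with submatrices `M_Delta`, `M_R`, `M_D` and scalars `D`,
#'   `Delta` (both in `[0, 1]`), `delta` (degrees, `[0, 180]`) and `psi`
#'   (degrees).
#' @export
#' @examples
#' mmpd(mm_linear_retarder(90, 0))$delta   # 90
#' mmpd(diag(c(1, 0.6, 0.6, 0.4)))$Delta   # 1 - 1.6/3
mmpd <- function(M) {
  check_mueller(M)
  if (abs(M[1, 1] - 1) > 1e-8)
    stop("'M' must be m11-normalized; call normalize_mueller() first",
         call. = FALSE)
  Dv <- M[1, 2:4]
  D <- sqrt(sum(Dv^2))
  if (D >= 1)
    stop(sprintf("diattenuation D = %.6g >= 1: M_D is not invertible", D),
         call. = FALSE)
  # diattenuator factor
  mD <- sqrt(1 - D^2) * diag(3)
  if (D > 0) mD <- mD + (1 - sqrt(1 - D^2)) * tcrossprod(Dv / D)
  M_D <- rbind(c(1, Dv), cbind(Dv, mD))
  # strip the diattenuator: M' = M %*% M_D^{-1}
  Mp <- M %*% solve(M_D)
  Pv <- Mp[2:4, 1]
  mp <- Mp[2:4, 2:4]
  # depolarizer block: signed symmetric square root of mp %*% t(mp)
  A <- mp %*% t(mp)
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  r <- sqrt(lam)
  s <- if (det(mp) < 0) -1 else 1
  num <- (r[1] + r[2] + r[3]) * A + (r[1] * r[2] * r[3]) * diag(3)
  den <- A + (r[1] * r[2] + r[2] * r[3] + r[3] * r[1]) * diag(3)
  m_Delta <- if (max(r) < 1e-12) matrix(0, 3, 3) else s * (pinv3(den) %*% num)
  M_Delta <- rbind(c(1, 0, 0, 0), cbind(Pv, m_Delta))
  # retarder block
  near_singular <- min(r) < 1e-9 * max(r, 1e-300)
  if (max(r) < 1e-12) {
    m_R <- diag(3)  # ideal depolarizer: retarder indeterminate, take identity
  } else if (near_singular) {
    warning("near-singular depolarizer block; retarder recovered by pseudo-inverse",
            call. = FALSE)
    m_R <- pinv3(m_Delta) %*% mp
  } else {
    m_R <- solve(m_Delta, mp)
  }
  M_R <- rbind(c(1, 0, 0, 0), cbind(c(0, 0, 0), m_R))
  Delta <- 1 - abs(sum(diag(m_Delta))) / 3
  arg <- sqrt((M_R[2, 2] + M_R[3, 3])^2 + (M_R[3, 2] - M_R[2, 3])^2) - 1
  delta <- acos(min(1, max(-1, arg))) * 180 / pi
  psi <- 0.5 * atan2(M_R[3, 2] - M_R[2, 3], M_R[2, 2] + M_R[3, 3]) * 180 / pi
  list(M_Delta = M_Delta, M_R = M_R, M_D = M_D,
       D = D, Delta = Delta, delta = delta, psi = psi)
}

#' Cloude coherency decomposition (MMCD)
#'
#' Computes the eigenvalues `lambda_1 >= ... >= lambda_4` of the coherency
#' matrix and the derived purity and entropy parameters:
#' `P1 = (l1 - l2)`, `P2 = (l1 + l2 - 2 l3)`, `P3 = (l1 + l2 + l3 - 3 l4)`
#' (all relative to `m11`), `PI = sqrt((P1^2 + P2^2 + P3^2) / 3)`,
#' `PDelta = sqrt((2 P1^2 + (2/3) P2^2 + (1/3) P3^2) / 3)` and the
#' polarization entropy `S = -sum(l_i log4 l_i)` with `0 log 0 = 0`.
#' `PDelta` coincides with the classical depolarization index
#' `sqrt((sum m_ij^2 - m11^2) / 3) / m11`.
#'
#' @param M m11-normalized Mueller matrix.
#' @param tol eigenvalues in `[-tol, 0)` (units of `m11`) are clipped to
#'   0; below `-tol` the matrix is rejected as unphysical. The strict
#'   default suits exact synthetic matrices; for measured or noisy
#'   matrices a tolerance at the noise scale (e.g. `0.05`) applies the
#'   standard clipping filter.
#' @return list with `lambda` (length 4, descending), `P1`, `P2`, `P3`,
#'   `PI`, `PDelta`, `S`.
#' @export
#' @examples
#' mmcd(diag(4))$S                  # 0: pure element
#' mmcd(diag(c(1, 0, 0, 0)))$S      # 1: ideal depolarizer
mmcd <- function(M, tol = 1e-9) {
  check_mueller(M)
  m11 <- M[1, 1]
  if (m11 <= 0) stop("m11 must be positive", call. = FALSE)
  lam <- coherency_eigenvalues(M)
  if (min(lam) < -tol * m11)
    stop(sprintf("unphysical input: coherency eigenvalue %.3g < -tol", min(lam)),
         call. = FALSE)
  lam <- pmax(lam, 0)
  l <- lam / m11
  P1 <- l[1] - l[2]
  P2 <- l[1] + l[2] - 2 * l[3]
  P3 <- l[1] + l[2] + l[3] - 3 * l[4]
  S <- -sum(ifelse(l > 0, l * log(l, base = 4), 0))
  list(lambda = lam, P1 = P1, P2 = P2, P3 = P3,
       PI = sqrt((P1^2 + P2^2 + P3^2) / 3),
       PDelta = sqrt((2 * P1^2 + (2 / 3) * P2^2 + (1 / 3) * P3^2) / 3),
       S = min(max(S, 0), 1))
}

#' Mueller matrix transformation parameters (MMT)
#'
#' Direct element combinations:
#' `t1 = 0.5 * sqrt((m22 - m33)^2 + (m23 + m32)^2)`,
#' `t2 = 0.5 * |m21 + m31|`, `t3 = 0.5 * sqrt(m42^2 + m43^2)`,
#' `b = 0.5 * (m22 + m33)`, and the normalized anisotropy
#' `A = 2 * b * t1 / (b^2 + t1^2)` (defined as 0 when `b = t1 = 0`).
#'
#' @param M m11-normalized Mueller matrix.
#' @return list with `t1`, `t2`, `t3`, `b`, `A`.
#' @export
mmt <- function(M) {
  check_mueller(M)
  t1 <- 0.5 * sqrt((M[2, 2] - M[3, 3])^2 + (M[2, 3] + M[3, 2])^2)
  t2 <- 0.5 * abs(M[2, 1] + M[3, 1])
  t3 <- 0.5 * sqrt(M[4, 2]^2 + M[4, 3]^2)
  b <- 0.5 * (M[2, 2] + M[3, 3])
  den <- b^2 + t1^2
  A <- if (den == 0) 0 else 2 * b * t1 / den
  list(t1 = t1, t2 = t2, t3 = t3, b = b, A = A)
}

#' Rotation-invariant parameters (RIP)
#'
#' `PL = sqrt(m21^2 + m31^2)` and `PC = m41` are the linear and circular
#' polarizance; `DL = sqrt(m12^2 + m13^2)` and `DC = m14` the linear and
#' circular diattenuation; `qL = sqrt(m42^2 + m43^2)` and
#' `rL = sqrt(m24^2 + m34^2)` the linear-to-circular and
#' circular-to-linear conversion capabilities.
#'
#' @param M m11-normalized Mueller matrix.
#' @return list with `PL`, `PC`, `DL`, `DC`, `qL`, `rL`.
#' @export
rip <- function(M) {
  check_mueller(M)
  list(PL = sqrt(M[2, 1]^2 + M[3, 1]^2), PC = M[4, 1],
       DL = sqrt(M[1, 2]^2 + M[1, 3]^2), DC = M[1, 4],
       qL = sqrt(M[4, 2]^2 + M[4, 3]^2), rL = sqrt(M[2, 4]^2 + M[3, 4]^2))
}

#' Quasi-uniform directions on the Poincare sphere
#'
#' Deterministic Fibonacci lattice; optional seeded jitter.
#'
#' @param n number of directions.
#' @param jitter logical; add small random angular jitter.
#' @param seed seed used when `jitter = TRUE`.
#' @return `n x 3` matrix of unit vectors.
#' @export
poincare_lattice <- function(n, jitter = FALSE, seed = NULL) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  phi <- 2 * pi * k * (sqrt(5) - 1) / 2
  if (jitter) {
    if (!is.null(seed)) set.seed(seed)
    z <- pmin(1, pmax(-1, z + stats::runif(n, -0.5, 0.5) * 2 / n))
    phi <- phi + stats::runif(n, -0.5, 0.5) * 2 * pi / n
  }
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

fit_quadric_ellipsoid <- function(P) {
  # algebraic least-squares fit of x'Qx + 2g'x = 1 to the point cloud P (n x 3)
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  X <- cbind(x^2, y^2, z^2, 2 * x * y, 2 * x * z, 2 * y * z, 2 * x, 2 * y, 2 * z)
  beta <- tryCatch(solve(crossprod(X), crossprod(X, rep(1, nrow(P)))),
                   error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  Q <- matrix(c(beta[1], beta[4], beta[5],
                beta[4], beta[2], beta[6],
                beta[5], beta[6], beta[3]), 3, 3)
  g <- beta[7:9]
  center <- tryCatch(as.vector(-solve(Q, g)), error = function(e) NULL)
  if (is.null(center)) return(NULL)
  kconst <- 1 - sum(g * center)
  ev <- eigen((Q + t(Q)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (kconst <= 0 || any(ev <= 0)) return(NULL)
  axes <- sort(sqrt(kconst / ev), decreasing = TRUE)
  list(axes = axes, center = center)
}

#' Global-polarization Stokes ellipsoid (GPSE)
#'
#' Samples `n_states` fully polarized input states quasi-uniformly on the
#' Poincare sphere, propagates them through `M`, normalizes the output
#' polarization vectors `p_k = (S1', S2', S3') / S0'`, and fits the
#' algebraic least-squares ellipsoid to the output cloud. Derived
#' parameters: `V = (a b c)^(1/3)` (polarization-maintaining ability),
#' `E = sqrt(1 - (b^2 + c^2) / (2 a^2))` (shape anisotropy),
#' `Dstar = sqrt(3 (x0^2 + y0^2 + z0^2)) / (a + b + c)` (center-offset
#' anisotropy), and the phase-delay statistics over the great-circle angles
#' `phi_k` between each input direction and its normalized output
#' direction: mean `RA` (radians), population variance `RD`, standardized
#' skewness `RS`.
#'
#' For matrices with first-row diattenuation the normalized output cloud is
#' only approximately an ellipsoid; the reported axes are those of the
#' least-squares fit. A collapsed short axis (`c < tol`), or a cloud for
#' which no ellipsoid can be fitted, is flagged `degenerate`; in that case
#' axes fall back to twice the principal-component standard deviations of
#' the cloud.
#'
#' @param M m11-normalized Mueller matrix.
#' @param n_states number of sampled states (>= 100; default 2000).
#' @param jitter,seed optional lattice jitter (see [poincare_lattice()]).
#' @param tol degeneracy threshold on the short semi-axis.
#' @return list with `a`, `b`, `c` (sorted semi-axes), `center`, `V`, `E`,
#'   `Dstar`, `RA`, `RD`, `RS`, `degenerate`.
#' @export
#' @examples
#' gpse(diag(4))$V                        # 1: sphere maps to itself
#' gpse(diag(c(1, 0.8, 0.6, 0.4)))$a      # 0.8
gpse <- function(M, n_states = 2000, jitter = FALSE, seed = NULL, tol = 1e-8) {
  check_mueller(M)
  if (n_states < 100) stop("'n_states' must be >= 100", call. = FALSE)
  Sdir <- poincare_lattice(n_states, jitter = jitter, seed = seed)
  Sin <- rbind(1, t(Sdir))                # 4 x n Stokes inputs
  Sout <- M %*% Sin
  S0 <- Sout[1, ]
  ok <- S0 > 1e-12
  P <- t(Sout[2:4, ok, drop = FALSE]) / S0[ok]
  fit <- fit_quadric_ellipsoid(P)
  degenerate <- FALSE
  if (is.null(fit) || fit$axes[3] < tol) {
    degenerate <- TRUE
    ctr <- colMeans(P)
    sdv <- sqrt(pmax(eigen(stats::cov(P), symmetric = TRUE,
                           only.values = TRUE)$values, 0))
    if (is.null(fit)) fit <- list(axes = 2 * sdv, center = ctr)
  }
  a <- fit$axes[1]; b <- fit$axes[2]; cc <- fit$axes[3]
  V <- (a * b * cc)^(1 / 3)
  E <- if (a > 0) sqrt(max(0, 1 - (b^2 + cc^2) / (2 * a^2))) else 0
  Dstar <- if (a + b + cc > 0)
    sqrt(3 * sum(fit$center^2)) / (a + b + cc) else 0
  # phase delays between input and normalized output directions
  pn <- sqrt(rowSums(P^2))
  good <- pn > 1e-12
  dots <- rowSums(Sdir[ok, , drop = FALSE][good, , drop = FALSE] *
                    (P[good, , drop = FALSE] / pn[good]))
  phi <- acos(pmin(1, pmax(-1, dots)))
  RA <- mean(phi)
  RD <- mean((phi - RA)^2)
  RS <- if (RD > 1e-18) mean((phi - RA)^3) / RD^1.5 else 0
  list(a = a, b = b, c = cc, center = fit$center,
       V = V, E = E, Dstar = Dstar, RA = RA, RD = RD, RS = RS,
       degenerate = degenerate)
}
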
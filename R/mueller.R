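#' Mueller matrices and elementary polarization elements
#'
#' A Mueller matrix is represented as a plain 4 x 4 numeric matrix. The
#' element `m[i, j]` is the element written `m_ij` in the polarimetry
#' literature (1-based, `m11` top-left). Most analysis functions expect the
#' matrix to be m11-normalized, i.e. `m[1, 1] == 1`; [normalize_mueller()]
#' produces that form.
#'
#' Angles are given in degrees at every API boundary, measured
#' counter-clockwise looking toward the source. A rotation of the sample
#' frame by `theta` mixes the linear Stokes components by `2 * theta`; the
#' retarder convention is the one for which a quarter-wave plate at axis 0
#' maps +S2 to -S3 (see [mm_linear_retarder()]), used consistently
#' throughout the package.
#'
#' @name mueller
NULL

#' Validate a Mueller matrix argument
#'
#' @param M object to check.
#' @return the matrix, invisibly, after basic shape checks.
#' @keywords internal
check_mueller <- function(M) {
  if (!is.matrix(M) || !is.numeric(M) || any(dim(M) != c(4L, 4L)))
    stop("'M' must be a numeric 4 x 4 matrix", call. = FALSE)
  if (any(!is.finite(M)))
    stop("'M' contains non-finite elements", call. = FALSE)
  invisible(M)
}

#' Normalize a Mueller matrix by its m11 element
#'
#' Divides every element by `m11` so that all Table-style polarization
#' parameter formulas (which assume `m11 = 1`) apply. Idempotent. A passive
#' medium satisfies `|m_ij| <= m11`; violations (possible for measured,
#' noisy matrices) trigger a warning, not an error.
#'
#' @param M 4 x 4 numeric Mueller matrix with `m11 > 0`.
#' @param warn warn when `|m_ij| > m11` after normalization (default TRUE).
#' @return the m11-normalized matrix.
#' @export
#' @examples
#' normalize_mueller(diag(c(2, 1, 1, 1)))
normalize_mueller <- function(M, warn = TRUE) {
  check_mueller(M)
  if (M[1, 1] <= 0)
    stop("invalid Mueller matrix: m11 must be positive, got ", M[1, 1],
         call. = FALSE)
  out <- M / M[1, 1]
  if (warn && max(abs(out)) > 1 + 1e-9)
    warning("element(s) exceed m11 in magnitude; matrix is not passive",
            call. = FALSE)
  out
}

#' Coherency matrix of a Mueller matrix
#'
#' Maps the Mueller matrix to the 4 x 4 Hermitian coherency matrix
#' `H = (1/4) * sum_ij m_ij (sigma_i x conj(sigma_j))` over the Pauli basis
#' `sigma_0 = I`, `sigma_1 = diag(1, -1)`, `sigma_2 = [[0,1],[1,0]]`,
#' `sigma_3 = [[0,-i],[i,0]]` (Cloude's ordering). The eigenvalues of `H`
#' are the basis of the Cloude decomposition and of the physical
#' realizability test.
#'
#' @param M 4 x 4 numeric Mueller matrix.
#' @return 4 x 4 complex Hermitian matrix.
#' @export
coherency_matrix <- function(M) {
  check_mueller(M)
  s <- list(
    diag(2) + 0i,
    matrix(c(1, 0, 0, -1), 2, 2) + 0i,
    matrix(c(0, 1, 1, 0), 2, 2) + 0i,
    matrix(c(0, 1i, -1i, 0), 2, 2)  # column-major: [[0,-i],[i,0]]
  )
  H <- matrix(0i, 4, 4)
  for (i in 1:4)
    for (j in 1:4)
      H <- H + M[i, j] * (s[[i]] %x% Conj(s[[j]]))
  H / 4
}

#' Physical realizability of a Mueller matrix
#'
#' A Mueller matrix is physically realizable when its coherency matrix
#' (see [coherency_matrix()]) is positive semi-definite. Small negative
#' eigenvalues within `tol` are accepted as numerical noise.
#'
#' @param M 4 x 4 numeric Mueller matrix (normalized or not).
#' @param tol tolerance on the minimum coherency eigenvalue
#'   (default `1e-9`, in units of `m11`).
#' @return logical; the minimum eigenvalue is attached as attribute
#'   `"min_eigenvalue"`.
#' @export
#' @examples
#' is_physical(diag(4))                     # TRUE
#' is_physical(diag(c(1, 1, 1, -1)))        # FALSE: coherency is indefinite
is_physical <- function(M, tol = 1e-9) {
  ev <- coherency_eigenvalues(M)
  structure(min(ev) >= -tol * max(abs(M[1, 1]), 1),
            min_eigenvalue = min(ev))
}

#' Eigenvalues of the coherency matrix, sorted descending
#' @inheritParams is_physical
#' @return numeric vector of length 4.
#' @export
coherency_eigenvalues <- function(M) {
  H <- coherency_matrix(M)
  sort(eigen((H + Conj(t(H))) / 2, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Mueller rotation matrix
#'
#' Frame-rotation matrix `R(theta)` mixing the linear Stokes components by
#' `2 * theta`.
#'
#' @param theta rotation angle in degrees.
#' @return 4 x 4 rotation Mueller matrix.
#' @export
mm_rotation <- function(theta) {
  t2 <- 2 * theta * pi / 180
  matrix(c(1, 0, 0, 0,
           0, cos(t2), -sin(t2), 0,
           0, sin(t2), cos(t2), 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' Rotate the sample frame of a Mueller matrix
#'
#' Returns `R(theta) %*% M %*% R(-theta)`: the Mueller matrix of the same
#' sample observed with its transverse axes rotated by `theta`. Rotation
#' preserves `m11`, `m44` and physical realizability, and is the operation
#' under which the rotation-invariant parameter systems are invariant.
#'
#' @param M 4 x 4 numeric Mueller matrix.
#' @param theta rotation angle, degrees.
#' @return rotated Mueller matrix.
#' @export
rotate_frame <- function(M, theta) {
  check_mueller(M)
  mm_rotation(theta) %*% M %*% mm_rotation(-theta)
}

#' Elementary Mueller matrices
#'
#' Standard textbook forms of the basic polarization elements, used as
#' building blocks of the phantom forward model and as oracles for the
#' decompositions.
#'
#' * `mm_linear_retarder(delta, axis)`: linear retarder with retardance
#'   `delta` (degrees) and fast axis at `axis` (degrees). At axis 0 the
#'   lower-right block is `[[cos d, sin d], [-sin d, cos d]]`, so a
#'   quarter-wave plate (`delta = 90`) has rows
#'   `[1,0,0,0; 0,1,0,0; 0,0,0,1; 0,0,-1,0]`.
#' * `mm_rotator(angle)`: circular retarder rotating the linear components
#'   by `angle` degrees.
#' * `mm_linear_diattenuator(q, axis)`: m11-normalized linear diattenuator
#'   with diattenuation `q` in `[0, 1]`; `q = 0` is the identity, `q = 1` a
#'   perfect polarizer.
#' * `mm_depolarizer(d1, d2, d3)`: diagonal depolarizer
#'   `diag(1, d1, d2, d3)` with principal transmittances in `[-1, 1]`.
#'
#' @param delta retardance in degrees.
#' @param axis fast-axis orientation in degrees.
#' @param angle rotation angle in degrees.
#' @param q diattenuation, in `[0, 1]`.
#' @param d1,d2,d3 principal polarization transmittances, each in `[-1, 1]`.
#' @return a 4 x 4 Mueller matrix; all outputs pass [is_physical()].
#' @name mm_elements
#' @examples
#' mm_linear_retarder(90, 0)
#' mm_depolarizer(0, 0, 0)     # ideal depolarizer
NULL

#' @rdname mm_elements
#' @export
mm_linear_retarder <- function(delta, axis = 0) {
  if (!is.finite(delta)) stop("'delta' must be finite", call. = FALSE)
  d <- delta * pi / 180
  M0 <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0,
                 0, 0, cos(d), sin(d),
                 0, 0, -sin(d), cos(d)), 4, 4, byrow = TRUE)
  if (axis == 0) M0 else rotate_frame(M0, axis)
}

#' @rdname mm_elements
#' @export
mm_rotator <- function(angle) mm_rotation(angle)

#' @rdname mm_elements
#' @export
mm_linear_diattenuator <- function(q, axis = 0) {
  if (!is.finite(q) || q < 0 || q > 1)
    stop("diattenuation 'q' must be in [0, 1]", call. = FALSE)
  r <- sqrt(1 - q^2)
  M0 <- matrix(c(1, q, 0, 0,
                 q, 1, 0, 0,
                 0, 0, r, 0,
                 0, 0, 0, r), 4, 4, byrow = TRUE)
  if (axis == 0) M0 else rotate_frame(M0, axis)
}

#' @rdname mm_elements
#' @export
mm_depolarizer <- function(d1, d2 = d1, d3 = d1) {
  d <- c(d1, d2, d3)
  if (any(!is.finite(d)) || any(abs(d) > 1))
    stop("depolarizer transmittances must lie in [-1, 1]", call. = FALSE)
  diag(c(1, d))
}

#' Stokes vector utilities
#'
#' A Stokes vector is a plain numeric vector `c(S0, S1, S2, S3)`.
#' `stokes_dop` returns the degree of polarization
#' `sqrt(S1^2 + S2^2 + S3^2) / S0`.
#'
#' @param S numeric length-4 Stokes vector with `S0 > 0`.
#' @return degree of polarization (non-negative scalar).
#' @export
stokes_dop <- function(S) {
  if (length(S) != 4L || S[1] <= 0)
    stop("'S' must be a length-4 Stokes vector with S0 > 0", call. = FALSE)
  sqrt(sum(S[2:4]^2)) / S[1]
}
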
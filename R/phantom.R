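#' Tissue-phantom forward simulator
#'
#' The simulated scene mirrors a fibrosis phantom: an anisotropic fiber
#' layer (retarding and weakly diattenuating, with a controllable
#' orientation) buried at an adjustable depth inside an isotropic
#' scattering suspension of polystyrene microspheres. The forward model is
#' phenomenological - a weighted two-path mixture rather than radiative
#' transport - constructed so that, as the layer moves deeper,
#' depolarization grows monotonically while the anisotropy signatures
#' (retardance, diattenuation) decay faster than the degrees of
#' polarization, and circular DOP outlives linear DOP. See the package
#' vignette for the rationale behind each default.
#'
#' @name phantom
NULL

# ---- Mie scattering -------------------------------------------------------

#' Mie efficiencies of a homogeneous sphere
#'
#' Bohren-Huffman series with downward recurrence for the logarithmic
#' derivative; valid for real or complex relative refractive index.
#'
#' @param m relative refractive index (sphere / medium).
#' @param x size parameter `pi * d * n_medium / lambda_vacuum`.
#' @return list with `Qext`, `Qsca`.
#' @export
mie_efficiencies <- function(m, x) {
  if (!is.finite(x) || x <= 0) stop("size parameter must be positive",
                                    call. = FALSE)
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2) + 1
  mx <- m * x
  nmx <- floor(max(nmax, Mod(mx))) + 16
  D <- complex(length.out = nmx + 1)
  for (n in nmx:1)
    D[n] <- n / mx - 1 / (D[n + 1] + n / mx)
  a <- complex(length.out = nmax)
  b <- complex(length.out = nmax)
  pn_m1 <- cos(x); pn <- sin(x)       # Riccati-Bessel psi_{-1}, psi_0
  cn_m1 <- -sin(x); cn <- cos(x)      # chi_{-1}, chi_0
  for (n in seq_len(nmax)) {
    pn_p1 <- (2 * n - 1) / x * pn - pn_m1
    cn_p1 <- (2 * n - 1) / x * cn - cn_m1
    xi_n <- pn_p1 - 1i * cn_p1
    xi_nm1 <- pn - 1i * cn
    Dn <- D[n + 1]
    a[n] <- ((Dn / m + n / x) * pn_p1 - pn) / ((Dn / m + n / x) * xi_n - xi_nm1)
    b[n] <- ((Dn * m + n / x) * pn_p1 - pn) / ((Dn * m + n / x) * xi_n - xi_nm1)
    pn_m1 <- pn; pn <- pn_p1
    cn_m1 <- cn; cn <- cn_p1
  }
  nn <- seq_len(nmax)
  list(Qext = 2 / x^2 * sum((2 * nn + 1) * Re(a + b)),
       Qsca = 2 / x^2 * sum((2 * nn + 1) * (Mod(a)^2 + Mod(b)^2)))
}

#' Specification of a microsphere suspension
#'
#' @param diameters sphere diameters per component.
#' @param volume_fractions solid volume fractions per component, each in
#'   `(0, 1)`.
#' @param wavelength_nm vacuum wavelength (default 625).
#' @param n_sphere,n_medium refractive indices (defaults: polystyrene
#'   1.587 and water 1.332 at 625 nm).
#' @param diameter_unit `"um"` (default) or `"nm"`.
#' @return object of class `suspension_spec`.
#' @export
suspension_spec <- function(diameters, volume_fractions, wavelength_nm = 625,
                            n_sphere = 1.587, n_medium = 1.332,
                            diameter_unit = c("um", "nm")) {
  diameter_unit <- match.arg(diameter_unit)
  d_um <- if (diameter_unit == "nm") diameters / 1000 else diameters
  if (length(d_um) != length(volume_fractions))
    stop("diameters and volume fractions must match in length", call. = FALSE)
  if (any(d_um <= 0)) stop("sphere diameters must be positive", call. = FALSE)
  if (any(volume_fractions <= 0 | volume_fractions >= 1))
    stop("volume fractions must lie in (0, 1)", call. = FALSE)
  structure(list(diameters_um = d_um, volume_fractions = volume_fractions,
                 wavelength_nm = wavelength_nm,
                 n_sphere = n_sphere, n_medium = n_medium),
            class = "suspension_spec")
}

#' Scattering coefficient of a sphere suspension by Mie theory
#'
#' Per component, the scattering coefficient under the
#' independent-scattering assumption is
#' `mu_s = (f / V_sphere) * Qsca * (pi d^2 / 4) = 1.5 f Qsca / d`, with
#' `Qsca` evaluated at the in-medium size parameter
#' `x = pi d n_medium / lambda_vacuum` and relative index
#' `n_sphere / n_medium`. Components add. Volume fractions above 10%
#' trigger a warning because dependent scattering (not modelled) then
#' reduces the effective coefficient.
#'
#' @param spec a [suspension_spec()].
#' @return list with `total` (cm^-1) and `per_component` (data frame with
#'   `diameter_um`, `volume_fraction`, `x`, `Qsca`, `mu_s_cm`).
#' @export
#' @examples
#' mie_mu_s(suspension_spec(c(5, 1), c(0.04, 0.001)))
mie_mu_s <- function(spec) {
  stopifnot(inherits(spec, "suspension_spec"))
  if (any(spec$volume_fractions > 0.1))
    warning("volume fraction above 10%: independent-scattering assumption weak",
            call. = FALSE)
  m <- spec$n_sphere / spec$n_medium
  lam_um <- spec$wavelength_nm / 1000
  rows <- lapply(seq_along(spec$diameters_um), function(i) {
    d <- spec$diameters_um[i]
    f <- spec$volume_fractions[i]
    x <- pi * d * spec$n_medium / lam_um
    Q <- mie_efficiencies(m, x)$Qsca
    data.frame(diameter_um = d, volume_fraction = f, x = x, Qsca = Q,
               mu_s_cm = 1.5 * f * Q / (d * 1e-4))
  })
  per <- do.call(rbind, rows)
  list(total = sum(per$mu_s_cm), per_component = per)
}

# ---- Layered forward model ------------------------------------------------

#' Parameters of the layered-phantom forward model
#'
#' The backscattering Mueller matrix at fiber-layer depth `d` (mm) is the
#' mixture
#' `M(d) = R(rot_rate d) [(1 - w(d)) M_bg + w(d) M_path(d)]` with
#' `w(d) = exp(-2 mu_att d)` weighting the photon fraction that reaches
#' the layer and returns, and `R` a net rotation of the polarization
#' plane accumulating with path length (multiple scattering rotates the
#' detected polarization state progressively with depth; this is the
#' mechanism behind the observed monotone growth of the rotation-angle
#' parameter RA). A left-multiplied rotator rigidly rotates the output
#' states on the Poincare sphere, so it changes only RA, RD and RS; the
#' rotation-invariant parameters (V, E, D-dagger, t1, Delta, Kc, the
#' Cloude eigenvalues, ...) are unaffected. The layer path is, inside the
#' fiber-orientation rotation sandwich,
#' `M_path(d) = R(theta) Depol(kL (1 + a/2), kL (1 - a/2), kC)
#' LR(delta_f k_A) LD(q_f k_A) R(-theta)` with `k_A = exp(-d/xi_A)`,
#' `a = aniso_f`, `kL = exp(-d/xi_L)`, `kC = exp(-d/xi_C)`.
#' The fiber layer maintains linearly polarized light differently along
#' and across the fiber direction (the constant fractional anisotropy
#' `aniso_f`; the resulting t1 signature decays as `w * kL`, faster than
#' the linear DOP itself because of the path weight), retards
#' (`delta_f`) and weakly diattenuates (`q_f`); the retardance and
#' diattenuation signatures decay on the fast scale `xi_A`. The
#' decay-length ordering `xi_A < xi_L < xi_C` encodes the phantom
#' phenomenology: anisotropy signatures decay fastest, linear DOP next,
#' circular DOP slowest.
#'
#' With the default parameters the model is physically realizable over
#' the whole working depth range 2-20 mm (and [layered_mueller()] checks
#' realizability on every call). Below about 2 mm the default anisotropy
#' exceeds the depolarizer's physical headroom (`kL * a <= 1 - kC`) and
#' [layered_mueller()] errors; shallow-depth studies need a smaller
#' `aniso_f` or a shorter `xi_C`.
#'
#' @param delta_f fiber retardance at zero depth, degrees.
#' @param aniso_f constant fractional difference in linear
#'   polarization-maintaining ability along vs across the fiber,
#'   `[0, 1)`; its depth decay comes from the `w * kL` factors.
#' @param q_f fiber diattenuation at zero depth, `[0, 1)`.
#' @param theta fiber orientation, degrees.
#' @param mu_att attenuation coefficient of the layer-path weight, mm^-1.
#' @param rot_rate net polarization-plane rotation per unit depth,
#'   degrees/mm; must satisfy `rot_rate * 20 < 90` so the state rotation
#'   `2 * rot_rate * d` stays below a half turn over the working depth
#'   range (beyond that the great-circle angle would wrap and RA would
#'   stop being monotone).
#' @param rot_jitter scale (degrees/mm) of the polarization-plane
#'   rotation disorder. The same scattering that accumulates the mean
#'   rotation `rot_rate * d` randomizes it, and the randomization rate
#'   itself grows as the returning light becomes more diffuse, so each
#'   simulated cell draws one rotation offset
#'   `N(0, (rot_jitter * d^3 / 400)^2)` (cubic in depth, normalized so
#'   that `rot_jitter` is the per-mm disorder at the 20 mm reference
#'   depth). The disorder is a medium-domain property, spatially
#'   correlated at the grid-cell scale, so unlike sensor noise it is
#'   not reduced by pixel averaging. It perturbs only the
#'   rotation-sensitive parameters RA, RD, RS and the DSPFPs built on
#'   RA, and increasingly so with depth - the mechanism behind the
#'   faster decay of anisotropy information.
#' @param xi_A,xi_L,xi_C decay lengths (mm) of the anisotropy signature
#'   and of the linear and circular DOP; must satisfy
#'   `xi_A < xi_L < xi_C`.
#' @param bg_linear,bg_circular residual linear/circular polarization of
#'   the isotropic background backscatter, `[0, 1)`; backscatter from the
#'   large-sphere suspension preserves circular polarization better than
#'   linear, so `bg_circular > bg_linear` by default.
#' @param noise_level relative frame-noise level for simulated
#'   measurements (default 0.01).
#' @param noise one of `"frames"` (noise applied to the simulated
#'   30-frame intensity stack, then reconstructed - the physically
#'   faithful path), `"elements"` (additive Gaussian directly on the
#'   Mueller elements) or `"none"`.
#' @param element_sigma standard deviation for `noise = "elements"`.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(delta_f = 6, aniso_f = 0.2, q_f = 0.1, theta = 20,
                           mu_att = 0.05, rot_rate = 3, rot_jitter = 0.25,
                           xi_A = 5, xi_L = 12,
                           xi_C = 35, bg_linear = 0.15, bg_circular = 0.3,
                           noise_level = 0.01,
                           noise = c("frames", "elements", "none"),
                           element_sigma = 0.005) {
  noise <- match.arg(noise)
  if (!(xi_A < xi_L && xi_L < xi_C))
    stop("decay lengths must satisfy xi_A < xi_L < xi_C", call. = FALSE)
  if (any(c(xi_A, xi_L, xi_C) <= 0) || mu_att <= 0)
    stop("all lengths and mu_att must be positive", call. = FALSE)
  if (rot_rate < 0 || rot_rate * 20 >= 90)
    stop("rot_rate must be in [0, 4.5) degrees/mm", call. = FALSE)
  if (rot_jitter < 0)
    stop("rot_jitter must be non-negative", call. = FALSE)
  if (q_f < 0 || q_f >= 1) stop("q_f must be in [0, 1)", call. = FALSE)
  if (aniso_f < 0 || aniso_f >= 1) stop("aniso_f must be in [0, 1)", call. = FALSE)
  if (bg_linear < 0 || bg_linear >= 1 || bg_circular < 0 || bg_circular >= 1)
    stop("background DOPs must be in [0, 1)", call. = FALSE)
  structure(list(delta_f = delta_f, aniso_f = aniso_f, q_f = q_f, theta = theta,
                 mu_att = mu_att, rot_rate = rot_rate,
                 rot_jitter = rot_jitter,
                 xi_A = xi_A, xi_L = xi_L, xi_C = xi_C,
                 bg_linear = bg_linear, bg_circular = bg_circular,
                 noise_level = noise_level, noise = noise,
                 element_sigma = element_sigma),
            class = "phantom_params")
}

#' Backscattering Mueller matrix of the layered phantom
#'
#' @param depth fiber-layer depth in mm (>= 0; `Inf` gives the pure
#'   background).
#' @param params a [phantom_params()].
#' @param theta fiber orientation override, degrees (defaults to
#'   `params$theta`); used by scenes with per-pixel orientation fields.
#' @return m11-normalized, physically realizable 4 x 4 Mueller matrix.
#' @export
layered_mueller <- function(depth, params = phantom_params(),
                            theta = params$theta) {
  if (!is.finite(depth) && is.infinite(depth) && depth > 0) {
    M_bg <- mm_depolarizer(params$bg_linear, params$bg_linear,
                           params$bg_circular)
    return(M_bg)
  }
  if (depth < 0) stop("'depth' must be non-negative", call. = FALSE)
  w <- exp(-2 * params$mu_att * depth)
  kA <- exp(-depth / params$xi_A)
  kL <- exp(-depth / params$xi_L)
  kC <- exp(-depth / params$xi_C)
  a <- params$aniso_f
  fiber <- mm_depolarizer(kL * (1 + a / 2), kL * (1 - a / 2), kC) %*%
    mm_linear_retarder(params$delta_f * kA) %*%
    mm_linear_diattenuator(params$q_f * kA)
  M_path <- rotate_frame(fiber, theta)
  M_bg <- mm_depolarizer(params$bg_linear, params$bg_linear,
                         params$bg_circular)
  M <- mm_rotator(params$rot_rate * depth) %*%
    ((1 - w) * M_bg + w * M_path)
  phys <- is_physical(M)
  if (!phys)
    stop(sprintf("parameter set yields unphysical matrix (min coherency eigenvalue %.3g)",
                 attr(phys, "min_eigenvalue")), call. = FALSE)
  M
}

# per-column polarization-plane rotation offsets (degrees) applied to a
# 16 x n stack of column-major vec'd Mueller matrices: left-multiplying
# by a rotator mixes matrix rows 2 and 3 only.
apply_rotation_disorder <- function(Mstack, eps_deg) {
  t2 <- 2 * eps_deg * pi / 180
  cs <- cos(t2); sn <- sin(t2)
  r2 <- c(2, 6, 10, 14); r3 <- c(3, 7, 11, 15)
  A <- Mstack[r2, , drop = FALSE]
  B <- Mstack[r3, , drop = FALSE]
  Mstack[r2, ] <- sweep(A, 2, cs, "*") - sweep(B, 2, sn, "*")
  Mstack[r3, ] <- sweep(A, 2, sn, "*") + sweep(B, 2, cs, "*")
  Mstack
}

# vectorized measurement noise over a 16 x n stack of Mueller matrices
# (column-major vec of each matrix). Returns the perturbed 16 x n stack.
apply_measurement_noise <- function(Mstack, params, cfg = drr_config()) {
  n <- ncol(Mstack)
  if (params$noise == "none" ||
      (params$noise == "frames" && params$noise_level == 0))
    return(Mstack)
  if (params$noise == "elements") {
    E <- matrix(stats::rnorm(16 * n, sd = params$element_sigma), 16, n)
    E[1, ] <- 0                      # m11 stays the normalization reference
    return(Mstack + E)
  }
  D <- drr_design_matrix(cfg)
  P <- {sv <- svd(D); sv$v %*% (t(sv$u) / sv$d)}
  F0 <- D %*% Mstack               # 30 x n noiseless frames
  Fn <- F0 * (1 + params$noise_level *
                matrix(stats::rnorm(length(F0)), nrow(F0), n))
  Mrec <- P %*% Fn
  sweep(Mrec, 2, Mrec[1, ], "/")   # renormalize by the recovered m11
}

#' Generate a depth-sweep dataset
#'
#' Emulates the sweep experiment: the fiber layer is stepped through
#' `depths`, each acquisition is a grid of cells whose Mueller matrices
#' share the forward model but carry independent measurement noise, and
#' the whole acquisition is repeated `repeats` times. The record count is
#' `prod(grid) * length(depths) * repeats` (the default 20 x 20 grid, ten
#' depths 2..20 mm and six repeats give 24,000 records).
#'
#' Each record is a grid *cell*, i.e. the average of the Mueller matrices
#' of `pixels_per_cell` camera pixels (a 20 x 20 grid over a 400 x 400
#' image gives 400 pixels per cell). Binning the raw intensity frames
#' over a homogeneous cell before the (linear) least-squares
#' reconstruction is exactly equivalent to reconstructing one matrix
#' with the frame noise scaled by `1/sqrt(pixels_per_cell)`, which is
#' how it is implemented.
#'
#' @param params a [phantom_params()].
#' @param depths depth grid in mm (default `seq(2, 20, by = 2)`).
#' @param grid cells per acquisition, `c(rows, cols)` (default 20 x 20).
#' @param repeats repeated acquisitions per depth (default 6).
#' @param pixels_per_cell camera pixels averaged into each cell record
#'   (default 400, a 20 x 20 pixel cell).
#' @param seed integer seed; the dataset is reproducible per seed.
#' @param n_states GPSE states per record.
#' @param eps DSPFP denominator floor.
#' @return object of class `depth_sweep`: list with `records` (data frame
#'   of feature records with `depth`, `repeat_id`, `cell_row`, `cell_col`)
#'   and the generating configuration.
#' @export
generate_depth_sweep <- function(params = phantom_params(),
                                 depths = seq(2, 20, by = 2),
                                 grid = c(20, 20), repeats = 6,
                                 pixels_per_cell = 400,
                                 seed = NULL, n_states = 300, eps = 1e-6) {
  if (!is.null(seed)) set.seed(seed)
  if (pixels_per_cell < 1) stop("'pixels_per_cell' must be >= 1", call. = FALSE)
  eff <- params
  eff$noise_level <- params$noise_level / sqrt(pixels_per_cell)
  eff$element_sigma <- params$element_sigma / sqrt(pixels_per_cell)
  ncell <- prod(grid)
  cfg <- drr_config()
  cells <- expand.grid(cell_row = seq_len(grid[1]), cell_col = seq_len(grid[2]))
  out <- vector("list", length(depths) * repeats)
  idx <- 1L
  for (rep_i in seq_len(repeats)) {
    for (d in depths) {
      M <- layered_mueller(d, params)
      Mstack <- matrix(as.vector(M), 16, ncell)
      if (params$rot_jitter > 0)
        Mstack <- apply_rotation_disorder(
          Mstack, stats::rnorm(ncell, 0, params$rot_jitter * d^3 / 400))
      Mn <- apply_measurement_noise(Mstack, eff, cfg)
      recs <- lapply(seq_len(ncell), function(i) {
        features_from_mueller(matrix(Mn[, i], 4, 4), n_states = n_states,
                              eps = eps)
      })
      block <- do.call(rbind, recs)
      block$depth <- d
      block$repeat_id <- rep_i
      block$cell_row <- cells$cell_row
      block$cell_col <- cells$cell_col
      out[[idx]] <- block
      idx <- idx + 1L
    }
  }
  structure(list(records = do.call(rbind, out),
                 depths = depths, grid = grid, repeats = repeats,
                 pixels_per_cell = pixels_per_cell,
                 params = params, seed = seed),
            class = "depth_sweep")
}

#' @export
print.depth_sweep <- function(x, ...) {
  cat(sprintf("<depth_sweep> %d records: %d x %d cells, depths %g..%g mm (%d), %d repeats\n",
              nrow(x$records), x$grid[1], x$grid[2],
              min(x$depths), max(x$depths), length(x$depths), x$repeats))
  invisible(x)
}

# ---- Scenes ---------------------------------------------------------------

#' Phantom scenes with fixed depth gradients
#'
#' Scene builders emulating the validation phantoms:
#' * `scene_dsp1()`: three vertical zones with a fixed depth step and a
#'   uniform fiber orientation (direction-sensitive);
#' * `scene_dsp2()`: four diagonally arranged zones with a fixed depth
#'   step, uniform orientation;
#' * `scene_dip()`: two concentric zones (disk + annulus) with a radial
#'   fiber orientation (direction-insensitive).
#'
#' @param zone1_depth depth of zone 1, mm.
#' @param step depth increment between zones, mm (default 2.5).
#' @param depths for `scene_dip`, the two zone depths.
#' @param size image size in pixels, `c(height, width)`.
#' @param theta uniform fiber orientation (degrees) for the
#'   direction-sensitive scenes.
#' @return object of class `scene_spec`: per-pixel `depth` matrix (NA
#'   where no fiber layer is present), per-pixel `theta` matrix and
#'   integer `zones` matrix.
#' @name scenes
NULL

new_scene <- function(depth, theta, zones, label) {
  d <- depth[is.finite(depth)]
  if (length(d) && (min(d) < 2 || max(d) > 20))
    stop("zone depths must lie within 2..20 mm", call. = FALSE)
  structure(list(depth = depth, theta = theta, zones = zones, label = label),
            class = "scene_spec")
}

#' @rdname scenes
#' @export
scene_dsp1 <- function(zone1_depth = 4, step = 2.5, size = c(120, 120),
                       theta = 20) {
  h <- size[1]; w <- size[2]
  zones <- matrix(rep(cut(seq_len(w), 3, labels = FALSE), each = h), h, w)
  depth <- matrix(zone1_depth + (zones - 1) * step, h, w)
  new_scene(depth, matrix(theta, h, w), zones, "DSP1")
}

#' @rdname scenes
#' @export
scene_dsp2 <- function(zone1_depth = 3, step = 2.5, size = c(120, 120),
                       theta = 20) {
  h <- size[1]; w <- size[2]
  top <- row(matrix(0, h, w)) <= h / 2
  left <- col(matrix(0, h, w)) <= w / 2
  zones <- matrix(0L, h, w)
  zones[top & left] <- 1L; zones[!top & !left] <- 2L
  zones[top & !left] <- 3L; zones[!top & left] <- 4L
  depth <- matrix(zone1_depth + (zones - 1) * step, h, w)
  new_scene(depth, matrix(theta, h, w), zones, "DSP2")
}

#' @rdname scenes
#' @export
scene_dip <- function(depths = c(3, 8), size = c(120, 120)) {
  h <- size[1]; w <- size[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ry <- (row(matrix(0, h, w)) - cy) / (h / 2)
  rx <- (col(matrix(0, h, w)) - cx) / (w / 2)
  rr <- sqrt(ry^2 + rx^2)
  zones <- matrix(NA_integer_, h, w)
  zones[rr <= 0.5] <- 1L
  zones[rr > 0.5 & rr <= 1] <- 2L
  depth <- matrix(NA_real_, h, w)
  depth[zones == 1L] <- depths[1]
  depth[zones == 2L] <- depths[2]
  theta <- atan2(ry, rx) * 180 / pi / 2 + 45  # radial fiber orientation
  new_scene(depth, theta, zones, "DIP")
}

#' @export
print.scene_spec <- function(x, ...) {
  zl <- sort(unique(x$zones[!is.na(x$zones)]))
  dz <- vapply(zl, function(z) mean(x$depth[x$zones == z], na.rm = TRUE),
               numeric(1))
  cat(sprintf("<scene_spec> %s, %d x %d px, zones at %s mm\n",
              x$label, nrow(x$depth), ncol(x$depth),
              paste(dz, collapse = "/")))
  invisible(x)
}

#' Render a phantom scene to a Mueller image
#'
#' Evaluates the layered forward model per pixel (using each pixel's zone
#' depth and local fiber orientation; pixels outside every zone show the
#' pure isotropic background) and applies seeded per-pixel measurement
#' noise.
#'
#' @param scene a [scene_spec()].
#' @param params a [phantom_params()].
#' @param seed integer seed for the per-pixel noise.
#' @return list of class `phantom_scene` with `image` (a
#'   [mueller_image()]), `truth` (per-pixel depth, NA outside zones) and
#'   `zones`.
#' @export
render_scene <- function(scene, params = phantom_params(), seed = NULL) {
  stopifnot(inherits(scene, "scene_spec"))
  if (!is.null(seed)) set.seed(seed)
  h <- nrow(scene$depth); w <- ncol(scene$depth)
  n <- h * w
  Mstack <- matrix(NA_real_, 16, n)
  key <- paste(scene$depth, round(scene$theta, 6))
  uk <- !duplicated(key)
  lut <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    d <- scene$depth[i]
    M <- layered_mueller(if (is.na(d)) Inf else d, params,
                         theta = scene$theta[i])
    assign(key[i], as.vector(M), envir = lut)
  }
  for (i in seq_len(n)) Mstack[, i] <- get(key[i], envir = lut)
  if (params$rot_jitter > 0) {
    # rotation disorder: one offset per 20 x 20 px medium domain (the
    # correlation scale of the disorder, matching the analysis cell),
    # scaled by the local depth
    s <- 20L
    zb <- matrix(stats::rnorm(ceiling(h / s) * ceiling(w / s)),
                 ceiling(h / s), ceiling(w / s))
    z <- zb[((seq_len(h) - 1L) %/% s) + 1L,
            ((seq_len(w) - 1L) %/% s) + 1L, drop = FALSE]
    dpx <- scene$depth
    dpx[is.na(dpx)] <- 0
    Mstack <- apply_rotation_disorder(
      Mstack, as.vector(z) * params$rot_jitter * as.vector(dpx)^3 / 400)
  }
  Mn <- apply_measurement_noise(Mstack, params)
  planes <- array(NA_real_, c(h, w, 16))
  ord <- as.vector(t(matrix(1:16, 4, 4)))  # column-major vec -> row-major planes
  for (p in 1:16) planes[, , p] <- matrix(Mn[ord[p], ], h, w)
  structure(list(image = mueller_image(planes),
                 truth = scene$depth, zones = scene$zones, scene = scene),
            class = "phantom_scene")
}
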
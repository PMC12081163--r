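#' Depth-sensitive polarization feature parameters (DSPFPs)
#'
#' Composite parameters built by multiplying degree-of-polarization (DOP)
#' sensitive and anisotropy-sensitive PBPs so that the product responds
#' monotonically to the depth of a buried fibrous layer:
#'
#' * `Kc = |m44|` - circular polarization-maintaining ability;
#' * `Ct = Kc^2 / t1`;
#' * `CtDelta = (Kc / t1) * Delta`;
#' * `RV = RA * V` (with `RA` in radians);
#' * `RVD = RA * V / (1 - Dstar)`.
#'
#' `t1` appears as a reciprocal because `Kc` and `t1` respond oppositely
#' to depth; `Dstar` enters as `1 / (1 - Dstar)` for the same reason.
#' Denominators are floored at `eps` and the record is flagged degenerate
#' rather than erroring, so image pipelines never abort on a pathological
#' pixel.
#'
#' @name dspfp
NULL

#' Circular polarization-maintaining ability
#'
#' @param M m11-normalized Mueller matrix.
#' @return `|m44|`, in `[0, 1]` for physical matrices.
#' @export
kc <- function(M) {
  check_mueller(M)
  abs(M[4, 4])
}

#' Compute the four DSPFPs from their PBP ingredients
#'
#' @param Kc circular polarization-maintaining ability, `[0, 1]`.
#' @param t1 MMT anisotropy parameter.
#' @param Delta MMPD depolarization.
#' @param RA GPSE mean phase delay, radians.
#' @param V GPSE polarization-maintaining ability.
#' @param Dstar GPSE center-offset anisotropy.
#' @param eps denominator floor (default 1e-6, normalized units).
#' @return list with `Ct`, `CtDelta`, `RV`, `RVD` and a logical
#'   `flag` set when any denominator was floored.
#' @export
#' @examples
#' compute_dspfp(Kc = 0.8, t1 = 0.4, Delta = 0.5, RA = 0.2, V = 0.5,
#'               Dstar = 0.5)
compute_dspfp <- function(Kc, t1, Delta, RA, V, Dstar, eps = 1e-6) {
  flag <- (t1 < eps) || (1 - Dstar < eps)
  t1f <- max(t1, eps)
  df <- max(1 - Dstar, eps)
  list(Ct = Kc^2 / t1f,
       CtDelta = (Kc / t1f) * Delta,
       RV = RA * V,
       RVD = RA * V / df,
       flag = flag)
}

#' All polarization features of one Mueller matrix
#'
#' Evaluates every PBP system ([mmpd()], [mmcd()], [mmt()], [rip()],
#' [gpse()]), `Kc`, and the four DSPFPs, returning a single one-row
#' data frame (a feature record). GPSE semi-axes are reported as `a`,
#' `b_dag` and `c` to keep the MMT `b` column unambiguous.
#'
#' @param M m11-normalized Mueller matrix.
#' @param n_states states used by the GPSE fit (default 500 in image
#'   pipelines; the fit is quasi-exact for true ellipsoids at any count).
#' @param eps DSPFP denominator floor.
#' @param realizability_tol tolerance (units of `m11`) for clipping small
#'   negative coherency eigenvalues, passed to [mmcd()]. The default 0.05
#'   accommodates measurement noise; matrices violating realizability
#'   beyond it are rejected.
#' @return one-row `data.frame`; column `flag` marks degenerate records.
#' @export
features_from_mueller <- function(M, n_states = 500, eps = 1e-6,
                                  realizability_tol = 0.05) {
  p <- mmpd(M)
  cdec <- mmcd(M, tol = realizability_tol)
  t <- mmt(M)
  r <- rip(M)
  g <- gpse(M, n_states = n_states)
  K <- kc(M)
  d <- compute_dspfp(K, t$t1, p$Delta, g$RA, g$V, g$Dstar, eps = eps)
  data.frame(
    D = p$D, Delta = p$Delta, delta = p$delta, psi = p$psi,
    P1 = cdec$P1, P2 = cdec$P2, P3 = cdec$P3, PI = cdec$PI,
    PDelta = cdec$PDelta, S = cdec$S,
    a = g$a, b_dag = g$b, c = g$c, V = g$V, E = g$E, Dstar = g$Dstar,
    RA = g$RA, RD = g$RD, RS = g$RS,
    t1 = t$t1, t2 = t$t2, t3 = t$t3, b = t$b, A = t$A,
    PL = r$PL, PC = r$PC, DL = r$DL, DC = r$DC, qL = r$qL, rL = r$rL,
    m44 = M[4, 4], Kc = K,
    Ct = d$Ct, CtDelta = d$CtDelta, RV = d$RV, RVD = d$RVD,
    flag = d$flag || g$degenerate)
}

#' Names of the PBP columns produced by [features_from_mueller()]
#' @return character vector (excludes the DSPFPs, `Kc`, `m44` and `flag`).
#' @export
pbp_names <- function() {
  c("D", "Delta", "delta", "psi",
    "P1", "P2", "P3", "PI", "PDelta", "S",
    "a", "b_dag", "c", "V", "E", "Dstar", "RA", "RD", "RS",
    "t1", "t2", "t3", "b", "A",
    "PL", "PC", "DL", "DC", "qL", "rL")
}

#' Grid-averaged feature records from a Mueller image
#'
#' The image is divided into a `grid[1] x grid[2]` grid of cells; the
#' Mueller elements within each cell are averaged first and the parameters
#' are computed on the averaged matrix (averaging parameters instead would
#' give different, noisier values - the order matters and is fixed here).
#' Trailing pixels that do not fill a whole cell are dropped with a
#' warning.
#'
#' @param img a [mueller_image()].
#' @param grid integer vector `c(rows, cols)` of grid cells (default
#'   `c(20, 20)`).
#' @param n_states,eps passed to [features_from_mueller()].
#' @return `data.frame` with one record per cell, plus `cell_row` and
#'   `cell_col` coordinates.
#' @export
features_from_image <- function(img, grid = c(20, 20), n_states = 500,
                                eps = 1e-6) {
  stopifnot(inherits(img, "mueller_image"))
  gr <- as.integer(grid[1]); gc <- as.integer(grid[2])
  ch <- img$height %/% gr; cw <- img$width %/% gc
  if (ch < 1 || cw < 1)
    stop("grid is finer than the image", call. = FALSE)
  if (img$height %% gr != 0 || img$width %% gc != 0)
    warning("image size not divisible by grid; trailing pixels dropped",
            call. = FALSE)
  out <- vector("list", gr * gc)
  idx <- 1L
  for (i in seq_len(gr)) {
    rs <- ((i - 1) * ch + 1):(i * ch)
    for (j in seq_len(gc)) {
      cs <- ((j - 1) * cw + 1):(j * cw)
      m <- apply(img$planes[rs, cs, , drop = FALSE], 3, mean)
      M <- matrix(m, 4, 4, byrow = TRUE)
      if (M[1, 1] != 1) M <- normalize_mueller(M, warn = FALSE)
      rec <- features_from_mueller(M, n_states = n_states, eps = eps)
      rec$cell_row <- i; rec$cell_col <- j
      out[[idx]] <- rec
      idx <- idx + 1L
    }
  }
  do.call(rbind, out)
}

#' Write a feature table to CSV
#'
#' Stable, documented column order: the output of
#' [features_from_mueller()] followed by any label/coordinate columns.
#'
#' @param features data frame of feature records.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
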
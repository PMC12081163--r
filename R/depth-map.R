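#' Two-dimensional depth-resolved imaging
#'
#' A fitted [depth_model()] applied cell-by-cell to a Mueller image yields
#' a depth map. Zone labels (from the scene layout) allow per-zone summary
#' statistics - the mean retrieved depth and, when the true depth is
#' known, the mean absolute error - computed over unflagged cells only.
#'
#' @name depth-mapping
NULL

block_reduce <- function(mat, grid, fun) {
  gr <- grid[1]; gc <- grid[2]
  ch <- nrow(mat) %/% gr; cw <- ncol(mat) %/% gc
  out <- matrix(NA, gr, gc)
  for (i in seq_len(gr))
    for (j in seq_len(gc))
      out[i, j] <- fun(mat[((i - 1) * ch + 1):(i * ch),
                           ((j - 1) * cw + 1):(j * cw)])
  out
}

block_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  tb <- table(x)
  as.numeric(names(tb)[which.max(tb)])
}

#' Predict a depth map from a Mueller image
#'
#' @param model a fitted [depth_model()].
#' @param img a [mueller_image()], or a `phantom_scene` from
#'   [render_scene()] (in which case zones and truth are taken from the
#'   scene unless given explicitly).
#' @param grid analysis grid `c(rows, cols)`; Mueller matrices are
#'   averaged per cell before feature computation.
#' @param zones optional zone labels: a pixel-level matrix matching the
#'   image (reduced to cells by majority) or a cell-level matrix.
#' @param truth optional true depth, same conventions as `zones` (reduced
#'   to cells by the mean).
#' @param n_states GPSE states per cell.
#' @return object of class `depth_map`: list with `depth` (cell matrix of
#'   retrieved depths, mm; flagged cells are NA), `zones`, `truth` and
#'   `zone_stats` (data frame: `zone`, `n`, `true_depth`, `mean_depth`,
#'   `mae`).
#' @export
predict_depth_map <- function(model, img, grid = c(20, 20), zones = NULL,
                              truth = NULL, n_states = 300) {
  stopifnot(inherits(model, "depth_model"))
  if (inherits(img, "phantom_scene")) {
    if (is.null(zones)) zones <- img$zones
    if (is.null(truth)) truth <- img$truth
    img <- img$image
  }
  feats <- features_from_image(img, grid = grid, n_states = n_states)
  pred <- predict(model, feats)
  depth <- matrix(NA_real_, grid[1], grid[2])
  depth[cbind(feats$cell_row, feats$cell_col)] <- pred
  reduce_arg <- function(x, fun) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    if (all(dim(x) == grid)) x else block_reduce(x, grid, fun)
  }
  zones_c <- reduce_arg(zones, block_mode)
  truth_c <- reduce_arg(truth, function(v) mean(v, na.rm = TRUE))
  zone_stats <- NULL
  if (!is.null(zones_c)) {
    zl <- sort(unique(zones_c[!is.na(zones_c)]))
    zone_stats <- do.call(rbind, lapply(zl, function(z) {
      in_z <- !is.na(zones_c) & zones_c == z & !is.na(depth)
      td <- if (!is.null(truth_c))
        mean(truth_c[!is.na(zones_c) & zones_c == z], na.rm = TRUE)
      else NA_real_
      data.frame(zone = z, n = sum(in_z),
                 true_depth = td,
                 mean_depth = mean(depth[in_z]),
                 mae = if (is.na(td)) NA_real_ else
                   mean(abs(depth[in_z] - td)))
    }))
  }
  structure(list(depth = depth, zones = zones_c, truth = truth_c,
                 zone_stats = zone_stats, grid = grid,
                 model = list(algorithm = model$algorithm,
                              features = model$features)),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> %d x %d cells, retrieved depth %.2f..%.2f mm\n",
              x$grid[1], x$grid[2],
              min(x$depth, na.rm = TRUE), max(x$depth, na.rm = TRUE)))
  if (!is.null(x$zone_stats)) {
    cat("Zone statistics (unflagged cells):\n")
    print(x$zone_stats, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a depth map
#'
#' @param x a `depth_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.depth_map <- function(x, ...) {
  z <- t(x$depth[rev(seq_len(nrow(x$depth))), , drop = FALSE])
  graphics::image(z, axes = FALSE, main = "retrieved depth (mm)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Write a depth map to disk
#'
#' The cell depth matrix goes to a 32-bit TIFF (with affine scaling
#' recorded in a JSON sidecar, as for Mueller images) and the zone summary
#' to a CSV next to it.
#'
#' @param dmap a `depth_map`.
#' @param path TIFF file path; the zone CSV gets suffix `.zones.csv`.
#' @return `path`, invisibly.
#' @export
write_depth_map <- function(dmap, path) {
  stopifnot(inherits(dmap, "depth_map"))
  d <- dmap$depth
  d[is.na(d)] <- -1
  lo <- min(d); hi <- max(d); if (hi <= lo) hi <- lo + 1
  tiff::writeTIFF((d - lo) / (hi - lo), path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(format = "mmdepth-depth-map", units = "mm",
                            scale_min = lo, scale_max = hi,
                            na_value = -1),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(dmap$zone_stats))
    utils::write.csv(dmap$zone_stats, paste0(path, ".zones.csv"),
                     row.names = FALSE)
  invisible(path)
}
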
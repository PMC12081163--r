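#' Depth-sensitivity screening statistics
#'
#' Three statistics summarize how well a polarization parameter tracks the
#' depth of the buried fiber layer over a depth sweep:
#'
#' * **PCC** - Pearson correlation between the per-depth mean response and
#'   depth, measuring monotonicity and linearity;
#' * **URI** - unsaturated response interval: the width (mm) from the first
#'   depth to the first depth at which the response change reaches 80% of
#'   its total range; a wider URI means sensitivity over a wider range;
#' * **RDS** - rank of data stability: per-depth standard deviations (on a
#'   per-parameter min-max normalized scale) are accumulated over depths
#'   and parameters are ranked; the most stable parameter scores 1, the
#'   least stable 0.
#'
#' @name screening
NULL

#' Pearson correlation of a parameter's depth response
#'
#' Computed on per-depth means (one point per depth), matching how the
#' URI and RDS statistics summarize a sweep. Returns `NA` with a warning
#' when either series has zero variance.
#'
#' @param values numeric responses.
#' @param depths depth label (mm) for each value.
#' @return correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pcc <- function(values, depths) {
  stopifnot(length(values) == length(depths))
  m <- tapply(values, depths, mean)
  d <- as.numeric(names(m))
  if (length(d) < 3) stop("need at least 3 distinct depths", call. = FALSE)
  if (stats::sd(m) == 0 || stats::sd(d) == 0) {
    warning("zero variance: PCC undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(as.numeric(m), d)
}

#' Unsaturated response interval
#'
#' @param mean_response per-depth mean response, one value per grid depth.
#' @param depth_grid depths (mm), sorted ascending, same length.
#' @return width in mm (`d* - depth_grid[1]`, where `d*` is the first
#'   depth at which the absolute change from the first depth reaches 80%
#'   of the total range). Attribute `"saturated"` is FALSE when the 80%
#'   level is never reached (the full width is returned) and the response
#'   is constant yields width 0 with `"saturated" = FALSE`.
#' @export
#' @examples
#' uri(seq(2, 20, 2) / 20, seq(2, 20, 2))   # 16: first crossing at 18 mm
uri <- function(mean_response, depth_grid) {
  stopifnot(length(mean_response) == length(depth_grid), length(depth_grid) >= 2,
            !is.unsorted(depth_grid))
  rng <- max(mean_response) - min(mean_response)
  if (rng == 0)
    return(structure(0, saturated = FALSE))
  change <- abs(mean_response - mean_response[1])
  hit <- which(change >= 0.8 * rng)
  if (length(hit) == 0)
    return(structure(depth_grid[length(depth_grid)] - depth_grid[1],
                     saturated = FALSE))
  structure(depth_grid[hit[1]] - depth_grid[1], saturated = TRUE)
}

#' Rank of data stability
#'
#' @param std_table matrix or data frame of per-depth standard deviations
#'   (rows = depths, columns = parameters), on a shared normalized scale.
#' @return named numeric vector of RDS scores in `[0, 1]`: parameters are
#'   ranked ascending by accumulated standard deviation and scored
#'   `1 - (rank - 1) / (N - 1)`; ties share the best rank.
#' @export
#' @examples
#' rds(rbind(c(0, 0.25, 0.5), c(0, 0.25, 0.5)))
rds <- function(std_table) {
  std_table <- as.matrix(std_table)
  N <- ncol(std_table)
  if (N < 2) stop("need at least 2 parameters to rank", call. = FALSE)
  totals <- colSums(std_table)
  rk <- rank(totals, ties.method = "min")
  out <- 1 - (rk - 1) / (N - 1)
  names(out) <- colnames(std_table)
  out
}

#' Screen parameters for depth sensitivity over a sweep
#'
#' For every parameter column: min-max normalizes the raw values to
#' `[-1, 1]`, computes per-depth normalized means and standard deviations,
#' and derives PCC, URI and RDS. This is the tabular analogue of the
#' screening heatmap used to shortlist depth-sensitive parameters.
#'
#' @param features data frame of feature records including a depth column.
#' @param depth_col name of the depth column (default `"depth"`).
#' @param params parameter columns to screen; defaults to every numeric
#'   column except the depth, flags and cell coordinates.
#' @return object of class `screening_table`: a data frame with one row per
#'   parameter (`param`, `pcc`, `uri`, `uri_saturated`, `rds`,
#'   `sd_total`), with the matrix of normalized per-depth mean responses
#'   attached as attribute `"response"`.
#' @export
screen_features <- function(features, depth_col = "depth", params = NULL) {
  if (!depth_col %in% names(features))
    stop("no '", depth_col, "' column in 'features'", call. = FALSE)
  depths <- features[[depth_col]]
  dgrid <- sort(unique(depths))
  if (length(dgrid) < 3)
    stop("dataset must span at least 3 depths", call. = FALSE)
  if (is.null(params)) {
    skip <- c(depth_col, "flag", "cell_row", "cell_col", "repeat_id")
    params <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                      skip)
  }
  resp <- matrix(NA_real_, length(dgrid), length(params),
                 dimnames = list(as.character(dgrid), params))
  sds <- resp
  stats_rows <- vector("list", length(params))
  for (i in seq_along(params)) {
    x <- features[[params[i]]]
    rng <- range(x)
    xn <- if (diff(rng) > 0) 2 * (x - rng[1]) / diff(rng) - 1 else x * 0
    mu <- tapply(xn, depths, mean)[as.character(dgrid)]
    sg <- tapply(xn, depths, stats::sd)[as.character(dgrid)]
    sg[is.na(sg)] <- 0
    resp[, i] <- mu
    sds[, i] <- sg
    p <- suppressWarnings(pcc(x, depths))
    u <- uri(as.numeric(mu), dgrid)
    stats_rows[[i]] <- data.frame(param = params[i], pcc = p,
                                  uri = as.numeric(u),
                                  uri_saturated = attr(u, "saturated"),
                                  sd_total = sum(sg))
  }
  tab <- do.call(rbind, stats_rows)
  tab$rds <- as.numeric(rds(sds))
  attr(tab, "response") <- resp
  class(tab) <- c("screening_table", class(tab))
  tab
}

#' @export
print.screening_table <- function(x, digits = 3, ...) {
  cat("Depth-sensitivity screening (", nrow(x), " parameters)\n\n", sep = "")
  df <- as.data.frame(x)[, c("param", "pcc", "uri", "rds")]
  df$pcc <- round(df$pcc, digits)
  df$rds <- round(df$rds, digits)
  print(df[order(-abs(df$pcc)), ], row.names = FALSE)
  invisible(x)
}
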
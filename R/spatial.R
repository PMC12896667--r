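#' Sample interval tracking points from per-second positions
#'
#' Emulates interval position sampling on an enclosure blueprint: starting
#' at the first observed second, one point is taken every `interval_s`
#' seconds, but only when a position is available at that exact second
#' (the animal is visible). Invisible interval starts are skipped, never
#' interpolated.
#'
#' @param positions Data frame with columns `time_s`, `x`, `y` (`NA`
#'   position = invisible) and optionally `individual`, `period`.
#' @param interval_s Sampling interval in seconds.
#' @return Data frame of tracking points (`individual`, `period`,
#'   `time_s`, `x`, `y`).
#' @examples
#' pos <- data.frame(time_s = 0:59, x = runif(60, 0, 100),
#'                   y = runif(60, 0, 100))
#' nrow(sample_points(pos))  # 4 points: seconds 0, 15, 30, 45
#' @export
sample_points <- function(positions, interval_s = 15) {
  stopifnot_scalar_number(interval_s, "interval_s", lower = 1)
  if (!nrow(positions)) {
    return(data.frame(individual = character(0), period = character(0),
                      time_s = integer(0), x = numeric(0),
                      y = numeric(0)))
  }
  t0 <- min(positions$time_s)
  at <- (positions$time_s - t0) %% interval_s == 0
  vis <- !is.na(positions$x) & !is.na(positions$y)
  sel <- positions[at & vis, , drop = FALSE]
  data.frame(individual = sel$individual %||% rep("", nrow(sel)),
             period = sel$period %||% rep(NA_character_, nrow(sel)),
             time_s = sel$time_s, x = sel$x, y = sel$y,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Enclosure-use heat map from tracking points
#'
#' Bins points into a regular grid over the blueprint, smooths the counts
#' with a truncated Gaussian kernel, and normalizes to unit mass, giving
#' a density surface of spatial use. Histogram-plus-smoothing is used
#' rather than kernel density estimation for exact mass control and
#' speed. Boundary points are clipped into the edge cells.
#'
#' @param points Data frame with `x`, `y` in blueprint pixels.
#' @param width,height Blueprint size in pixels.
#' @param nx,ny Grid size in cells.
#' @param sigma_cells Gaussian smoothing bandwidth in cells; `0` disables
#'   smoothing.
#' @return A list of class `heatmap_grid`: `values` (`ny x nx` matrix,
#'   row 1 = top of the image, summing to 1), grid spec fields, and
#'   `n_points`.
#' @export
heatmap_grid <- function(points, width = 1920, height = 1080,
                         nx = 64, ny = 36, sigma_cells = 2) {
  if (!nrow(points)) stop("cannot build a heat map from zero points",
                          call. = FALSE)
  ix <- pmin(pmax(floor(points$x / (width / nx)), 0), nx - 1) + 1
  iy <- pmin(pmax(floor(points$y / (height / ny)), 0), ny - 1) + 1
  counts <- matrix(0, ny, nx)
  for (k in seq_along(ix)) counts[iy[k], ix[k]] <- counts[iy[k], ix[k]] + 1
  sm <- gaussian_smooth(counts, sigma_cells)
  structure(list(values = sm / sum(sm), width = width, height = height,
                 nx = nx, ny = ny, sigma_cells = sigma_cells,
                 n_points = nrow(points)),
            class = "heatmap_grid")
}

# separable truncated-Gaussian convolution (kernel radius 3 sigma);
# mass is conserved exactly by the caller's final normalization
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - r); hi <- min(n, i + r)
      kk <- k[(lo - i + r + 1L):(hi - i + r + 1L)]
      out[i] <- sum(v[lo:hi] * kk / sum(kk))   # renormalized at edges
    }
    out
  }
  mat <- apply(mat, 2L, conv1)
  t(apply(mat, 1L, conv1))
}

#' Difference between two heat maps
#'
#' Cell-wise difference of the two normalized densities, highlighting
#' where spatial use increased (`a` over `b`, positive) or decreased
#' (negative). The result sums to zero.
#'
#' @param a,b [heatmap_grid()] objects with identical grid specs.
#' @return A `heatmap_grid` whose `values` are signed and sum to 0; the
#'   `type` field is `"difference"`.
#' @export
difference_map <- function(a, b) {
  stopifnot(inherits(a, "heatmap_grid"), inherits(b, "heatmap_grid"))
  same <- a$nx == b$nx && a$ny == b$ny && a$width == b$width &&
    a$height == b$height
  if (!same) stop("heat maps have different grid specs", call. = FALSE)
  structure(list(values = a$values / sum(a$values) -
                   b$values / sum(b$values),
                 width = a$width, height = a$height, nx = a$nx,
                 ny = a$ny, sigma_cells = a$sigma_cells,
                 n_points = a$n_points + b$n_points,
                 type = "difference"),
            class = "heatmap_grid")
}

#' Blueprint coordinates of a heat map's densest cell
#'
#' @param grid A `heatmap_grid` (density or difference).
#' @return Named vector `c(x, y)`: the center of the cell with the
#'   largest value, in blueprint pixels.
#' @export
heatmap_peak <- function(grid) {
  idx <- which(grid$values == max(grid$values), arr.ind = TRUE)[1L, ]
  c(x = (idx[["col"]] - 0.5) * grid$width / grid$nx,
    y = (idx[["row"]] - 0.5) * grid$height / grid$ny)
}

#' Write a heat map as a CSV matrix
#' @param grid A `heatmap_grid`.
#' @param path File path.
#' @export
write_heatmap_csv <- function(grid, path) {
  utils::write.table(grid$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf("<heatmap_grid> %dx%d cells over %dx%d px, %d points%s\n",
              x$nx, x$ny, x$width, x$height, x$n_points,
              if (identical(x$type, "difference")) " (difference)" else ""))
  invisible(x)
}

#' Plot a heat map with a blue-to-red density ramp
#'
#' Red marks the highest density of tracking points, blue the lowest.
#' For a difference map the ramp is centered on zero.
#'
#' @param x A `heatmap_grid`.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.heatmap_grid <- function(x, main = NULL, ...) {
  pal <- grDevices::colorRampPalette(c("blue", "cyan", "yellow",
                                       "red"))(64)
  # image() draws y upward; flip rows so row 1 (image top) plots on top
  z <- t(x$values[rev(seq_len(x$ny)), , drop = FALSE])
  if (identical(x$type, "difference")) {
    lim <- max(abs(z)); zlim <- c(-lim, lim)
  } else {
    zlim <- range(z)
  }
  graphics::image(seq(0, x$width, length.out = x$nx),
                  seq(0, x$height, length.out = x$ny), z,
                  col = pal, zlim = zlim, xlab = "x (px)",
                  ylab = "y (px)", main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Render a heat map to a PNG file
#' @param grid A `heatmap_grid`.
#' @param path Output PNG path.
#' @param width_px,height_px Image size in pixels.
#' @param main Plot title.
#' @export
render_heatmap_png <- function(grid, path, width_px = 800,
                               height_px = 480, main = NULL) {
  grDevices::png(path, width = width_px, height = height_px)
  on.exit(grDevices::dev.off())
  plot(grid, main = main)
  invisible(path)
}
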
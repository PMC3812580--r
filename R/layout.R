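# Sensor placement: centroidal Voronoi tessellation of the sensing surface.

#' One Lloyd iteration on a rectangle
#'
#' Assigns every cell of a fine grid covering the `width` x `height`
#' rectangle to its nearest generator point and moves each generator to the
#' centroid of its Voronoi region. A centroidal Voronoi tessellation is
#' exactly a fixed point of this map.
#'
#' @param points A data frame with columns `x`, `y` (generator positions,
#'   corner-origin coordinates).
#' @param width,height Rectangle dimensions (same length unit as `points`).
#' @param resolution Grid cells along the longer side. Default 200.
#' @return A tibble of updated `x`, `y` positions, same row order.
#' @export
lloyd_step <- function(points, width, height, resolution = 200L) {
  if (width <= 0 || height <= 0) abort("width and height must be positive")
  nx <- if (width >= height) resolution else max(2L, round(resolution * width / height))
  ny <- if (height > width) resolution else max(2L, round(resolution * height / width))
  gx <- (seq_len(nx) - 0.5) * width / nx
  gy <- (seq_len(ny) - 0.5) * height / ny
  grid <- expand.grid(x = gx, y = gy)
  d2 <- outer(grid$x, points$x, "-")^2 + outer(grid$y, points$y, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  tibble(
    x = vapply(seq_len(nrow(points)), function(k) mean(grid$x[nearest == k]), numeric(1)),
    y = vapply(seq_len(nrow(points)), function(k) mean(grid$y[nearest == k]), numeric(1))
  )
}

#' Optimal planar sensor layout on a rectangular surface
#'
#' Places `n` sensors so that they induce a centroidal Voronoi tessellation
#' of the surface: each sensor sits at the center of mass of its own Voronoi
#' tile, minimising the mean distance from any point of the tile to its
#' sensor. For the deployed case `n = 4` on a rectangle this is the analytic
#' quadrant-centroid layout at `(width/4, height/4)` offsets from the
#' corners; other `n` are solved numerically by Lloyd iteration.
#'
#' Coordinates are corner-origin, x rightward, y upward.
#'
#' @param width,height Surface dimensions (e.g. millimetres; the deployed
#'   plate is 420 x 300 mm).
#' @param n Number of sensors. Default 4.
#' @param max_iter,tol Lloyd iteration controls for the generic case.
#' @return A tibble with columns `sensor`, `x`, `y`.
#' @examples
#' sensor_layout(420, 300)
#' @export
sensor_layout <- function(width, height, n = 4L, max_iter = 200L, tol = 1e-6) {
  if (width <= 0 || height <= 0) abort("width and height must be positive")
  if (n == 4L) {
    pos <- tibble(
      x = c(width / 4, 3 * width / 4, width / 4, 3 * width / 4),
      y = c(height / 4, height / 4, 3 * height / 4, 3 * height / 4)
    )
  } else {
    set.seed(n)  # deterministic seeding of the iteration
    pos <- tibble(x = runif(n, 0, width), y = runif(n, 0, height))
    for (i in seq_len(max_iter)) {
      nxt <- lloyd_step(pos, width, height)
      if (max(abs(nxt$x - pos$x), abs(nxt$y - pos$y)) < tol * max(width, height)) {
        pos <- nxt
        break
      }
      pos <- nxt
    }
  }
  tibble(sensor = seq_len(n), x = pos$x, y = pos$y)
}
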
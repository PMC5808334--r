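# Delaunay triangulation by the Bowyer-Watson incremental algorithm.
# Small point sets only (electrode montages); O(n^2) is fine there.
# Returns a matrix of point-index triples (rows = triangles).
delaunay_triangulation <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("need at least 3 points to triangulate")
  # collinearity check: all cross products (p2-p1) x (pi-p1) ~ 0
  cross <- (x[2] - x[1]) * (y - y[1]) - (y[2] - y[1]) * (x - x[1])
  scale2 <- max(diff(range(x)), diff(range(y)))^2
  if (all(abs(cross) < 1e-12 * scale2))
    stop("electrode positions are collinear; cannot triangulate")
  # super-triangle enclosing everything
  cx <- mean(range(x)); cy <- mean(range(y))
  r <- max(diff(range(x)), diff(range(y))) * 10 + 1
  px <- c(x, cx - 2 * r, cx + 2 * r, cx)
  py <- c(y, cy - r, cy - r, cy + 2 * r)
  super <- n + 1:3
  tris <- matrix(super, nrow = 1)
  circum <- function(t) {
    ax <- px[t[1]]; ay <- py[t[1]]; bx <- px[t[2]]; by <- py[t[2]]
    cx2 <- px[t[3]]; cy2 <- py[t[3]]
    d <- 2 * (ax * (by - cy2) + bx * (cy2 - ay) + cx2 * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy2) + (bx^2 + by^2) * (cy2 - ay) +
             (cx2^2 + cy2^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx2 - bx) + (bx^2 + by^2) * (ax - cx2) +
             (cx2^2 + cy2^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  cc <- t(apply(tris, 1, circum))
  for (i in seq_len(n)) {
    bad <- which((px[i] - cc[, 1])^2 + (py[i] - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12))
    if (length(bad) == 0L) bad <- 1L  # numerical fallback; should not happen
    # boundary polygon of the bad-triangle cavity = edges appearing once
    edges <- do.call(rbind, lapply(bad, function(b) {
      t <- tris[b, ]
      rbind(sort(c(t[1], t[2])), sort(c(t[2], t[3])), sort(c(t[3], t[1])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(boundary, i)
    tris <- rbind(tris, newt)
    cc <- rbind(cc, t(apply(newt, 1, circum)))
  }
  keep <- apply(tris, 1, function(t) !any(t %in% super))
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0L)
    stop("electrode positions are degenerate; cannot triangulate")
  tris
}

# Barycentric coordinates of points (qx, qy) in triangle (x[1:3], y[1:3]).
barycentric_coords <- function(x, y, qx, qy) {
  d <- (y[2] - y[3]) * (x[1] - x[3]) + (x[3] - x[2]) * (y[1] - y[3])
  l1 <- ((y[2] - y[3]) * (qx - x[3]) + (x[3] - x[2]) * (qy - y[3])) / d
  l2 <- ((y[3] - y[1]) * (qx - x[3]) + (x[1] - x[3]) * (qy - y[3])) / d
  cbind(l1, l2, 1 - l1 - l2)
}

# Piecewise-linear interpolation of `values` at query points over a
# triangulation; NA outside the convex hull.
interpolate_tri <- function(x, y, values, tris, qx, qy, tol = 1e-9) {
  out <- rep(NA_real_, length(qx))
  for (t in seq_len(nrow(tris))) {
    v <- tris[t, ]
    todo <- which(is.na(out))
    if (length(todo) == 0L) break
    L <- barycentric_coords(x[v], y[v], qx[todo], qy[todo])
    inside <- L[, 1] >= -tol & L[, 2] >= -tol & L[, 3] >= -tol
    if (any(inside))
      out[todo[inside]] <- L[inside, , drop = FALSE] %*% values[v]
  }
  out
}

#' Interpolated scalp topography of per-electrode values
#'
#' Delaunay-triangulates the electrode positions and interpolates the
#' per-electrode values piecewise-linearly (barycentric coordinates within
#' each triangle) onto a regular grid. At each electrode position the
#' interpolant reproduces that electrode's value exactly; grid points
#' outside the convex hull of the montage are `NA`.
#'
#' @param values named (or plain) numeric vector of per-electrode values,
#'   e.g. decoding accuracies.
#' @param positions `n x 2` matrix of scalp-plane coordinates, same order as
#'   `values` (see [standard_montage()]).
#' @param grid_n grid resolution per axis (default 64).
#' @return object of class `topography`: grid axes `x`, `y`, value matrix
#'   `z` (`grid_n x grid_n`, `NA` outside the hull), plus `triangles`,
#'   `positions`, `values`. Use [predict.topography()] for arbitrary query
#'   points and `plot()` to draw the map.
#' @export
topography_map <- function(values, positions, grid_n = 64) {
  positions <- matrix(as.numeric(as.matrix(positions)), ncol = 2)
  if (nrow(positions) != length(values))
    stop("one position per value required")
  tris <- delaunay_triangulation(positions[, 1], positions[, 2])
  gx <- seq(min(positions[, 1]), max(positions[, 1]), length.out = grid_n)
  gy <- seq(min(positions[, 2]), max(positions[, 2]), length.out = grid_n)
  g <- expand.grid(x = gx, y = gy)
  z <- interpolate_tri(positions[, 1], positions[, 2], as.numeric(values),
                       tris, g$x, g$y)
  structure(list(x = gx, y = gy, z = matrix(z, grid_n, grid_n),
                 triangles = tris, positions = positions,
                 values = as.numeric(values),
                 names = names(values)),
            class = "topography")
}

#' Evaluate a topography at arbitrary points
#' @param object a `topography`.
#' @param newdata `m x 2` matrix of query coordinates.
#' @param ... unused.
#' @return numeric vector of interpolated values (`NA` outside the hull).
#' @export
predict.topography <- function(object, newdata, ...) {
  newdata <- matrix(as.numeric(as.matrix(newdata)), ncol = 2)
  interpolate_tri(object$positions[, 1], object$positions[, 2],
                  object$values, object$triangles,
                  newdata[, 1], newdata[, 2])
}

#' @export
print.topography <- function(x, ...) {
  cat(sprintf("<topography> %d electrodes, %d triangles, %dx%d grid, values %.3g..%.3g\n",
              nrow(x$positions), nrow(x$triangles), length(x$x), length(x$y),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.topography <- function(x, main = "topography", ...) {
  image(x$x, x$y, x$z, col = hcl.colors(64, "YlOrRd", rev = TRUE),
        asp = 1, xlab = "", ylab = "", main = main, ...)
  points(x$positions, pch = 20, cex = 0.7)
  if (!is.null(x$names))
    text(x$positions, labels = x$names, pos = 3, cex = 0.55)
  invisible(x)
}
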
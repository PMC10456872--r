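#' Shoelace area and centroid of a simple polygon
#'
#' Signed shoelace sum `A_s = 1/2 * sum_i (x_i y_{i+1} - x_{i+1} y_i)` and
#' the matching centroid sums with the `1/(6 A_s)` factor.  The returned
#' area is the absolute value, so the result does not depend on vertex
#' orientation.
#'
#' @param vertices two-column matrix of polygon vertices in traversal order
#'   (at least 3 rows; the polygon must be simple).
#' @return list with `area` (>= 0), `centroid` (`c(Cx, Cy)`) and
#'   `signed_area` (positive for counter-clockwise order).
#' @export
shoelace <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3) stop("need at least 3 vertices")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a_signed <- sum(cross) / 2
  if (a_signed == 0)
    return(list(area = 0, centroid = c(mean(x), mean(y)), signed_area = 0))
  cx <- sum((x + xn) * cross) / (6 * a_signed)
  cy <- sum((y + yn) * cross) / (6 * a_signed)
  list(area = abs(a_signed), centroid = c(cx, cy), signed_area = a_signed)
}

#' Fit a containment polygon to a 2-D point cloud
#'
#' Points are ranked by Euclidean distance to the cloud centroid and the
#' closest `ceiling(containment * n)` are kept; the polygon is the convex
#' hull of the kept points (counter-clockwise).  The hull is decomposed
#' into a triangle fan from the polygon centroid to consecutive vertex
#' pairs, with per-triangle areas, angles and point occupancies (see
#' [triangle_morphology()]).
#'
#' @param points two-column matrix of `(x, y)` points.
#' @param containment fraction of points the polygon must contain
#'   (default 0.95).
#' @return an object of class `polygon_model`: `vertices` (CCW),
#'   `centroid`, `area`, `n_vertices`, `n_kept`, `kept` (row indices of
#'   retained points), `triangles` (data frame), `degenerate`.  With fewer
#'   than 4 points or a collinear cloud a degenerate model (area 0, no
#'   triangles) is returned.
#' @export
fit_polygon <- function(points, containment = 0.95) {
  p <- as.matrix(points)
  if (length(p) == 0) p <- matrix(numeric(0), ncol = 2)
  if (ncol(p) != 2) stop("points must be a two-column matrix")
  if (!is.numeric(containment) || containment <= 0 || containment > 1)
    stop("containment must lie in (0, 1]")
  degen <- function(kept) {
    structure(list(vertices = NULL, centroid = c(NA_real_, NA_real_),
                   area = 0, n_vertices = 0L, n_kept = length(kept),
                   kept = kept, triangles = NULL, degenerate = TRUE,
                   containment = containment),
              class = "polygon_model")
  }
  n <- nrow(p)
  if (n < 4) return(degen(seq_len(n)))
  ctr <- colMeans(p)
  d <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
  keep_n <- ceiling(containment * n)
  kept <- order(d)[seq_len(keep_n)]
  q <- p[kept, , drop = FALSE]
  hull <- rev(grDevices::chull(q[, 1], q[, 2]))   # chull is clockwise
  if (length(hull) < 3) return(degen(kept))
  verts <- q[hull, , drop = FALSE]
  sl <- shoelace(verts)
  if (sl$area < .Machine$double.eps * max(1, sum(abs(q))))
    return(degen(kept))
  model <- structure(list(vertices = unname(verts), centroid = sl$centroid,
                          area = sl$area, n_vertices = nrow(verts),
                          n_kept = keep_n, kept = kept, triangles = NULL,
                          degenerate = FALSE, containment = containment),
                     class = "polygon_model")
  model$triangles <- triangle_morphology(model, q)
  model
}

#' @export
print.polygon_model <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<polygon_model: degenerate (%d points)>\n", x$n_kept))
  } else {
    cat(sprintf(
      "<polygon_model: %d vertices, area %.4g, centroid (%.3g, %.3g), %d points kept>\n",
      x$n_vertices, x$area, x$centroid[1], x$centroid[2], x$n_kept))
  }
  invisible(x)
}

# interior angle (degrees) at vertex a of triangle (a, b, c)
.angle_at <- function(a, b, c) {
  u <- b - a; v <- c - a
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Triangle-fan morphology of a containment polygon
#'
#' Decomposes the polygon into triangles `(C, V_i, V_{i+1})` from the
#' centroid `C` to consecutive vertex pairs, reporting per triangle: the
#' shoelace area `Ar_i`; the angle `beta_i` at the centroid; `theta_i`,
#' the mean of the two base angles at `V_i` and `V_{i+1}`; and the number
#' of kept points falling inside (boundary points are assigned to the
#' lowest-index triangle).
#'
#' @param model a non-degenerate [fit_polygon()] model.
#' @param points two-column matrix of the kept points to assign to
#'   triangles.
#' @return data frame with columns `Ar`, `occupancy`, `beta`, `theta`;
#'   triangles with a zero-length centroid-vertex edge carry `NA` angles.
#' @export
triangle_morphology <- function(model, points) {
  stopifnot(inherits(model, "polygon_model"))
  if (model$degenerate) stop("degenerate polygon model")
  v <- model$vertices
  ctr <- model$centroid
  nv <- nrow(v)
  p <- as.matrix(points)
  np <- nrow(p)
  nxt <- c(2:nv, 1L)
  Ar <- beta <- theta <- numeric(nv)
  for (i in seq_len(nv)) {
    A <- ctr; B <- v[i, ]; C <- v[nxt[i], ]
    Ar[i] <- shoelace(rbind(A, B, C))$area
    beta[i] <- .angle_at(A, B, C)
    theta[i] <- mean(c(.angle_at(B, C, A), .angle_at(C, A, B)))
  }
  # occupancy: sign tests against the three CCW edges, first triangle wins
  occupancy <- integer(nv)
  if (np > 0) {
    scale <- max(1, max(abs(p)))
    tol <- 1e-9 * scale^2
    unassigned <- rep(TRUE, np)
    crossmin <- matrix(NA_real_, np, nv)
    for (i in seq_len(nv)) {
      A <- ctr; B <- v[i, ]; C <- v[nxt[i], ]
      e1 <- (B[1] - A[1]) * (p[, 2] - A[2]) - (B[2] - A[2]) * (p[, 1] - A[1])
      e2 <- (C[1] - B[1]) * (p[, 2] - B[2]) - (C[2] - B[2]) * (p[, 1] - B[1])
      e3 <- (A[1] - C[1]) * (p[, 2] - C[2]) - (A[2] - C[2]) * (p[, 1] - C[1])
      crossmin[, i] <- pmin(e1, e2, e3)
      inside <- unassigned & e1 >= -tol & e2 >= -tol & e3 >= -tol
      occupancy[i] <- occupancy[i] + sum(inside)
      unassigned[inside] <- FALSE
    }
    # numerical stragglers go to the triangle they violate least
    if (any(unassigned)) {
      for (j in which(unassigned)) {
        i <- which.max(crossmin[j, ])
        occupancy[i] <- occupancy[i] + 1L
      }
    }
  }
  data.frame(Ar = Ar, occupancy = occupancy, beta = beta, theta = theta)
}

#' @export
plot.polygon_model <- function(x, points = NULL, ...) {
  if (x$degenerate) stop("cannot plot a degenerate polygon model")
  v <- rbind(x$vertices, x$vertices[1, ])
  if (!is.null(points))
    graphics::plot(points, pch = 16, cex = 0.5, col = "grey50",
                   xlab = "dBBI", ylab = "dTT", ...)
  else
    graphics::plot(v, type = "n", xlab = "dBBI", ylab = "dTT", ...)
  graphics::lines(v, col = "steelblue", lwd = 2)
  graphics::segments(x$centroid[1], x$centroid[2],
                     x$vertices[, 1], x$vertices[, 2],
                     col = "steelblue", lty = 3)
  graphics::points(x$centroid[1], x$centroid[2], pch = 3, col = "firebrick")
  invisible(x)
}
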
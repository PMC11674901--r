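#' Ordered 3D polyline
#'
#' @param points numeric matrix, one 3D point (mm) per row.  Closed
#'   polylines store each point once (no duplicated closing point).
#' @param closed logical; closed polylines need at least 3 points.
#' @return an object of class `polyline3d`.
#' @export
polyline3d <- function(points, closed = FALSE) {
  points <- matrix(as.numeric(points), ncol = 3, dimnames = NULL)
  if (closed && nrow(points) >= 2 &&
      sqrt(sum((points[1, ] - points[nrow(points), ])^2)) < 1e-12)
    points <- points[-nrow(points), , drop = FALSE]
  if (closed && nrow(points) < 3)
    stop("closed polyline needs at least 3 distinct points")
  structure(list(points = points, closed = isTRUE(closed)),
            class = "polyline3d")
}

#' @export
print.polyline3d <- function(x, ...) {
  cat(sprintf("<polyline3d: %d points, %s, length %.4g mm>\n",
              nrow(x$points), if (x$closed) "closed" else "open",
              polyline_length(x)))
  invisible(x)
}

#' Total arc length of a polyline (mm)
#' @param poly a [polyline3d].
#' @return numeric scalar.
#' @export
polyline_length <- function(poly) {
  p <- poly$points
  if (poly$closed) p <- rbind(p, p[1, ])
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

#' Resample a polyline uniformly by arc length
#' @param poly a [polyline3d].
#' @param n number of output points.
#' @return a [polyline3d] with `n` points (closed polylines: `n` points
#'   around the loop, start preserved).
#' @export
resample_polyline <- function(poly, n = 256) {
  p <- poly$points
  if (poly$closed) p <- rbind(p, p[1, ])
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate polyline")
  target <- if (poly$closed) seq(0, total, length.out = n + 1)[-(n + 1)]
            else seq(0, total, length.out = n)
  out <- cbind(approx(s, p[, 1], xout = target, ties = "ordered")$y,
               approx(s, p[, 2], xout = target, ties = "ordered")$y,
               approx(s, p[, 3], xout = target, ties = "ordered")$y)
  polyline3d(out, closed = poly$closed)
}

#' Centre point of a curve
#'
#' Arithmetic mean of the arc-length-resampled points, so vertex density
#' does not bias the centre.
#' @param poly a [polyline3d].
#' @param n resampling density.
#' @return numeric length-3 point.
#' @export
polyline_centre <- function(poly, n = 256) {
  colMeans(resample_polyline(poly, n)$points)
}

# Shoelace area and perimeter of a closed polyline projected into its
# section plane with normal `normal`.
polygon_area_perimeter <- function(poly, normal) {
  p <- poly$points
  nrm <- normal / sqrt(sum(normal^2))
  # build in-plane basis
  a <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * nrm) * nrm
  u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  x <- p %*% u
  y <- p %*% v
  xs <- c(x, x[1]); ys <- c(y, y[1])
  area <- abs(sum(xs[-length(xs)] * ys[-1] - xs[-1] * ys[-length(ys)])) / 2
  per <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
  list(area = area, perimeter = per)
}

#' Right-handed orthonormal frame
#'
#' @param origin 3D point (mm).
#' @param axes 3x3 matrix whose rows are the x, y, z unit axes.
#' @return object of class `frame3d`.
#' @export
frame3d <- function(origin = c(0, 0, 0), axes = diag(3)) {
  origin <- as.numeric(origin)
  axes <- matrix(as.numeric(axes), 3, 3)
  g <- axes %*% t(axes)
  if (max(abs(g - diag(3))) > 1e-9)
    stop("frame axes are not orthonormal")
  if (det(axes) < 0)
    stop("frame axes are not right-handed")
  structure(list(origin = origin, axes = axes), class = "frame3d")
}

#' Build a frame from an origin, a z axis and a hint for x
#'
#' `x_hint` is orthogonalised against `z`; y completes the right-handed
#' triad.
#' @param origin 3D point.
#' @param z direction of the frame z axis (normalised internally).
#' @param x_hint approximate x direction.
#' @return a [frame3d].
#' @export
frame_from_zx <- function(origin, z, x_hint) {
  z <- z / sqrt(sum(z^2))
  x <- x_hint - sum(x_hint * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop("x hint parallel to z axis (degenerate frame)")
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  frame3d(origin, rbind(x, y, z))
}

#' @export
print.frame3d <- function(x, ...) {
  cat("<frame3d origin", sprintf("% .4g", x$origin), ">\n")
  invisible(x)
}

#' Rigid motion mapping one frame onto another
#'
#' Applies the rigid transform that carries frame `from` onto frame `to`
#' (axes to axes, origin to origin).  Pairwise distances are preserved.
#'
#' @param mesh a [trimesh] (or [polyline3d]).
#' @param from,to [frame3d] objects.
#' @return object of the same class, transformed.
#' @export
transform_to_frame <- function(mesh, from, to) {
  R <- t(to$axes) %*% from$axes
  tr <- to$origin - as.numeric(R %*% from$origin)
  apply_rigid(mesh, R, tr)
}

#' Apply a rigid motion x -> R x + t
#' @param obj a [trimesh] or [polyline3d].
#' @param R 3x3 rotation matrix.
#' @param t translation vector.
#' @return transformed object.
#' @export
apply_rigid <- function(obj, R, t = c(0, 0, 0)) {
  if (inherits(obj, "trimesh")) {
    obj$vertices <- sweep(obj$vertices %*% t(R), 2, -t)
    obj
  } else if (inherits(obj, "polyline3d")) {
    obj$points <- sweep(obj$points %*% t(R), 2, -t)
    obj
  } else if (inherits(obj, "frame3d")) {
    frame3d(as.numeric(R %*% obj$origin) + t, obj$axes %*% t(R))
  } else stop("unsupported object")
}

#' Oriented box
#' @param frame a [frame3d] at the box centre.
#' @param extents positive lengths along the frame axes (mm).
#' @return object of class `oriented_box`.
#' @export
oriented_box <- function(frame, extents) {
  extents <- as.numeric(extents)
  if (any(extents < 0)) stop("extents must be non-negative")
  structure(list(frame = frame, extents = extents), class = "oriented_box")
}

#' Face centres of an oriented box
#'
#' Faces are numbered 1..6 as -x, +x, -y, +y, -z, +z of the box frame.
#' @param box an [oriented_box].
#' @return list with `centres` (6x3 matrix) and `normals` (6x3, outward).
#' @export
box_faces <- function(box) {
  ax <- box$frame$axes
  e <- box$extents / 2
  centres <- matrix(NA_real_, 6, 3)
  normals <- matrix(NA_real_, 6, 3)
  k <- 1
  for (d in 1:3) {
    for (s in c(-1, 1)) {
      normals[k, ] <- s * ax[d, ]
      centres[k, ] <- box$frame$origin + s * e[d] * ax[d, ]
      k <- k + 1
    }
  }
  list(centres = centres, normals = normals)
}

#' Volume of an oriented box
#' @param box an [oriented_box].
#' @return numeric scalar (mm^3).
#' @export
box_volume <- function(box) prod(box$extents)
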
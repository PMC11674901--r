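# Parametric mesh constructors.  All produce consistent outward winding.

#' Axis-aligned box mesh
#' @param lo,hi opposite corners (mm).
#' @param name label.
#' @return watertight [trimesh] (12 triangles).
#' @export
box_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1), name = "box") {
  V <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # corner order: 1=(0,0,0) 2=(1,0,0) 3=(0,1,0) 4=(1,1,0) 5..8 top
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),       # bottom (z = lo), outward -z
    c(5, 6, 7), c(6, 8, 7),       # top
    c(1, 2, 5), c(2, 6, 5),       # y = lo
    c(3, 7, 4), c(4, 7, 8),       # y = hi
    c(1, 5, 3), c(3, 5, 7),       # x = lo
    c(2, 4, 6), c(4, 8, 6))       # x = hi
  trimesh(V, F, name = name)
}

#' UV-sphere mesh
#' @param centre centre point; @param radius radius (mm).
#' @param n_theta,n_phi angular resolution.
#' @param name label.
#' @return watertight [trimesh].
#' @export
sphere_mesh <- function(centre = c(0, 0, 0), radius = 1, n_theta = 48,
                        n_phi = 24, name = "sphere") {
  grid_revolve(profile_r = function(phi) radius * sin(phi),
               profile_z = function(phi) radius * cos(phi),
               v = seq(0, pi, length.out = n_phi + 1),
               n_theta = n_theta, centre = centre, name = name,
               close_poles = TRUE)
}

# Surface of revolution around +z with poles optionally closed.
# v parametrises the profile; r(v) >= 0, z(v).
grid_revolve <- function(profile_r, profile_z, v, n_theta, centre = c(0, 0, 0),
                         name = "rev", close_poles = TRUE) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  r <- profile_r(v); z <- profile_z(v)
  nv <- length(v)
  Vs <- list(); idx <- matrix(NA_integer_, nv, n_theta)
  count <- 0L
  pole <- integer(nv)
  for (i in seq_len(nv)) {
    if (r[i] < 1e-12 && close_poles) {
      count <- count + 1L
      Vs[[length(Vs) + 1]] <- c(0, 0, z[i])
      pole[i] <- count
    } else {
      Vs[[length(Vs) + 1]] <- cbind(r[i] * cos(th), r[i] * sin(th), z[i])
      idx[i, ] <- count + seq_len(n_theta)
      count <- count + n_theta
    }
  }
  V <- do.call(rbind, Vs)
  F <- NULL
  for (i in seq_len(nv - 1)) {
    a <- idx[i, ]; b <- idx[i + 1, ]
    if (!is.na(a[1]) && !is.na(b[1])) {
      an <- c(a[-1], a[1]); bn <- c(b[-1], b[1])
      F <- rbind(F, cbind(a, b, bn), cbind(a, bn, an))
    } else if (is.na(a[1]) && !is.na(b[1])) {   # pole at i (top)
      bn <- c(b[-1], b[1])
      F <- rbind(F, cbind(pole[i], b, bn))
    } else if (!is.na(a[1]) && is.na(b[1])) {   # pole at i+1 (bottom)
      an <- c(a[-1], a[1])
      F <- rbind(F, cbind(a, pole[i + 1], an))
    }
  }
  m <- trimesh(sweep(V, 2, -centre), F, name = name)
  # ensure outward orientation for closed surfaces
  if (is_watertight(m) && mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Closed right-cylinder mesh
#' @param radius,height cylinder dimensions (mm); axis +z, base at z = 0.
#' @param n_theta circumferential segments.
#' @param n_z axial segments of the wall.
#' @param centre translation applied to the result.
#' @param name label.
#' @param caps logical; FALSE gives an open tube (two boundary loops).
#' @return [trimesh]; watertight when `caps = TRUE`.
#' @export
cylinder_mesh <- function(radius = 1, height = 1, n_theta = 64, n_z = 8,
                          centre = c(0, 0, 0), name = "cylinder",
                          caps = TRUE) {
  if (caps) {
    v <- c(0, seq(0, 1, length.out = n_z + 1), 1)
    r <- c(0, rep(radius, n_z + 1), 0)
    z <- c(height, rev(seq(0, height, length.out = n_z + 1)), 0)
    grid_revolve(function(p) r, function(p) z, seq_along(v), n_theta,
                 centre = centre, name = name, close_poles = TRUE)
  } else {
    zs <- seq(height, 0, length.out = n_z + 1)
    grid_revolve(function(p) rep(radius, length(p)), function(p) zs,
                 seq_len(n_z + 1), n_theta, centre = centre, name = name,
                 close_poles = FALSE)
  }
}

#' Torus mesh
#' @param R major radius; @param r minor radius (mm).  Axis +z.
#' @param n_u,n_v resolution.
#' @param name label.
#' @return watertight [trimesh].
#' @export
torus_mesh <- function(R = 3, r = 1, n_u = 64, n_v = 32, name = "torus") {
  u <- seq(0, 2 * pi, length.out = n_u + 1)[-(n_u + 1)]
  v <- seq(0, 2 * pi, length.out = n_v + 1)[-(n_v + 1)]
  V <- NULL
  for (j in seq_along(v)) {
    rr <- R + r * cos(v[j]); zz <- r * sin(v[j])
    V <- rbind(V, cbind(rr * cos(u), rr * sin(u), zz))
  }
  idx <- function(j, i) (j - 1) * n_u + i
  F <- NULL
  for (j in seq_len(n_v)) {
    jn <- if (j == n_v) 1 else j + 1
    i <- seq_len(n_u); inx <- c(i[-1], 1)
    F <- rbind(F, cbind(idx(j, i), idx(jn, i), idx(jn, inx)),
               cbind(idx(j, i), idx(jn, inx), idx(j, inx)))
  }
  m <- trimesh(V, F, name = name)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Circle polyline
#' @param radius radius (mm); @param centre centre; @param n points.
#' @param normal plane normal (circle constructed in this plane).
#' @return closed [polyline3d].
#' @export
circle_polyline <- function(radius, centre = c(0, 0, 0), n = 256,
                            normal = c(0, 0, 1)) {
  nrm <- normal / sqrt(sum(normal^2))
  a <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * nrm) * nrm; u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  p <- outer(radius * cos(th), u) + outer(radius * sin(th), v)
  polyline3d(sweep(p, 2, -centre), closed = TRUE)
}

# Closed solid from a stack of closed section curves with identical point
# counts and matching correspondence: lateral quad strips plus centroid-fan
# caps at both ends.  curves: list of K x 3 matrices ordered along the axis.
solid_from_sections <- function(curves, name = "solid", cap_first = TRUE,
                                cap_last = TRUE) {
  K <- nrow(curves[[1]])
  stopifnot(all(vapply(curves, nrow, 1L) == K))
  V <- do.call(rbind, curves)
  nL <- length(curves)
  F <- NULL
  for (lev in seq_len(nL - 1)) {
    a <- (lev - 1) * K + seq_len(K)
    b <- lev * K + seq_len(K)
    an <- c(a[-1], a[1]); bn <- c(b[-1], b[1])
    F <- rbind(F, cbind(a, b, bn), cbind(a, bn, an))
  }
  if (cap_first) {
    c0 <- colMeans(curves[[1]])
    V <- rbind(V, c0); ci <- nrow(V)
    a <- seq_len(K); an <- c(a[-1], a[1])
    F <- rbind(F, cbind(ci, a, an))
  }
  if (cap_last) {
    c1 <- colMeans(curves[[nL]])
    V <- rbind(V, c1); ci <- nrow(V)
    a <- (nL - 1) * K + seq_len(K); an <- c(a[-1], a[1])
    F <- rbind(F, cbind(ci, an, a))
  }
  m <- trimesh(V, F, name = name)
  if (is_watertight(m) && mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}
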
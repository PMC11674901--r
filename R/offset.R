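#' Offset a mesh along its vertex normals
#'
#' Displaces every vertex by `distance` along its area-weighted vertex
#' normal, keeping the connectivity.  `direction = "outward"` moves along
#' the normals, `"inward"` against them.  A warning with the flip count is
#' issued when the offset inverts face normals (local self-intersection).
#'
#' @param mesh a [trimesh].
#' @param distance offset distance (mm), > 0.
#' @param direction `"inward"` or `"outward"` relative to the mesh normals.
#' @return a [trimesh] with displaced vertices.
#' @export
offset_along_normals <- function(mesh, distance,
                                 direction = c("outward", "inward")) {
  direction <- match.arg(direction)
  if (!is.numeric(distance) || distance <= 0)
    stop("offset distance must be > 0")
  s <- if (direction == "inward") -1 else 1
  vn <- vertex_normals(mesh)
  out <- mesh
  out$vertices <- mesh$vertices + s * distance * vn
  fn0 <- face_normals(mesh)
  fn1 <- face_normals(out)
  flips <- sum(rowSums(fn0 * fn1) < 0)
  if (flips > 0)
    warning(sprintf("offset flipped %d face normal(s): local self-intersection",
                    flips))
  out
}

#' Loft a triangulated strip between two curves
#'
#' Both curves are resampled to `n` points by arc length; the seam is chosen
#' by the cyclic shift (and orientation reversal, if needed) minimising the
#' sum of squared point distances; quads are split along the shorter
#' diagonal.
#'
#' @param curve_a,curve_b [polyline3d] objects, both closed or both open.
#' @param n common resampling count.
#' @param name label.
#' @return an open [trimesh] strip between the curves.
#' @export
loft <- function(curve_a, curve_b, n = 256, name = "loft") {
  if (curve_a$closed != curve_b$closed)
    stop("cannot loft a closed curve to an open curve")
  A <- resample_polyline(curve_a, n)$points
  B <- resample_polyline(curve_b, n)$points
  if (max(abs(A - B)) < 1e-12) stop("identical curves: degenerate loft")
  if (curve_a$closed) {
    B <- align_correspondence(A, B)
  }
  strip_between(A, B, closed = curve_a$closed, name = name)
}

# cyclic shift + optional reversal of B minimising sum |A - B|^2
align_correspondence <- function(A, B) {
  n <- nrow(A)
  best <- Inf; bestB <- B
  for (rev in c(FALSE, TRUE)) {
    Br <- if (rev) B[c(1, n:2), , drop = FALSE] else B
    # cross-correlation over cyclic shifts
    for (s in 0:(n - 1)) {
      idx <- ((seq_len(n) - 1 + s) %% n) + 1
      val <- sum((A - Br[idx, , drop = FALSE])^2)
      if (val < best) {
        best <- val; bestB <- Br[idx, , drop = FALSE]
      }
    }
  }
  bestB
}

# quad strip between matched point rows, split along the shorter diagonal
strip_between <- function(A, B, closed, name = "loft") {
  n <- nrow(A)
  V <- rbind(A, B)
  i <- seq_len(if (closed) n else n - 1)
  inx <- if (closed) c(i[-1], 1) else i + 1
  a <- i; an <- inx; b <- i + n; bn <- inx + n
  d1 <- rowSums((V[a, , drop = FALSE] - V[bn, , drop = FALSE])^2)
  d2 <- rowSums((V[an, , drop = FALSE] - V[b, , drop = FALSE])^2)
  use1 <- d1 <= d2
  F <- rbind(cbind(a[use1], b[use1], bn[use1]),
             cbind(a[use1], bn[use1], an[use1]),
             cbind(a[!use1], b[!use1], an[!use1]),
             cbind(an[!use1], b[!use1], bn[!use1]))
  trimesh(V, F, name = name)
}

# Loft through a stack of curves with exact point correspondence (no
# resampling): rows of consecutive matrices are connected 1:1.
loft_stack_exact <- function(mats, closed = TRUE, name = "loft") {
  V <- do.call(rbind, mats)
  K <- nrow(mats[[1]])
  F <- NULL
  for (lev in seq_len(length(mats) - 1)) {
    a <- (lev - 1) * K + seq_len(K)
    b <- lev * K + seq_len(K)
    i <- seq_len(if (closed) K else K - 1)
    inx <- if (closed) c(i[-1], 1) else i + 1
    F <- rbind(F, cbind(a[i], b[i], b[inx]), cbind(a[i], b[inx], a[inx]))
  }
  trimesh(V, F, name = name)
}

#' Mean closest-surface distance from points to a mesh
#' @param points matrix of query points.
#' @param mesh target [trimesh].
#' @return numeric vector of unsigned distances (mm).
#' @export
distance_to_mesh <- function(points, mesh) {
  cpp_point_mesh_distance(matrix(points, ncol = 3), mesh$vertices, mesh$faces)
}
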
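#' Intersect a mesh with a plane
#'
#' Returns the intersection polylines of the mesh surface with a plane given
#' as a [frame3d] (origin + z axis as normal).  Crossing points are computed
#' per mesh edge, so chains are exact and shared between adjacent faces;
#' chains closing on themselves are marked closed.
#'
#' @param mesh a [trimesh].
#' @param plane a [frame3d]; the plane passes through `plane$origin` with
#'   normal `plane$axes[3, ]`.
#' @return list of [polyline3d]; empty when the plane misses the mesh.
#' @export
section_with_plane <- function(mesh, plane) {
  nrm <- plane$axes[3, ]
  nrm <- nrm / sqrt(sum(nrm^2))
  d <- as.numeric(mesh$vertices %*% nrm) - sum(plane$origin * nrm)
  # avoid exact-zero vertices (grazing): nudge consistently
  eps <- 1e-12 * max(1, max(abs(d)))
  d[abs(d) < eps] <- eps
  F <- mesh$faces
  s1 <- d[F[, 1]]; s2 <- d[F[, 2]]; s3 <- d[F[, 3]]
  cross12 <- (s1 > 0) != (s2 > 0)
  cross23 <- (s2 > 0) != (s3 > 0)
  cross31 <- (s3 > 0) != (s1 > 0)
  hit <- cross12 | cross23 | cross31
  if (!any(hit)) return(list())
  Fh <- F[hit, , drop = FALSE]
  c12 <- cross12[hit]; c23 <- cross23[hit]; c31 <- cross31[hit]
  n <- nrow(mesh$vertices)
  ekey <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    (as.numeric(lo) - 1) * n + as.numeric(hi)
  }
  # per-face: exactly two crossing edges
  e_a <- ifelse(c12, ekey(Fh[, 1], Fh[, 2]),
                ekey(Fh[, 2], Fh[, 3]))
  e_b <- ifelse(c12 & c23, ekey(Fh[, 2], Fh[, 3]),
                ekey(Fh[, 3], Fh[, 1]))
  keys <- unique(c(e_a, e_b))
  # crossing point for each unique edge
  lo <- floor((keys - 1) / n) + 1
  hi <- keys - (lo - 1) * n
  t <- d[lo] / (d[lo] - d[hi])
  P <- mesh$vertices[lo, , drop = FALSE] +
    (mesh$vertices[hi, , drop = FALSE] - mesh$vertices[lo, , drop = FALSE]) * t
  # project exactly onto the plane (removes the epsilon nudge residue)
  P <- P - outer(as.numeric(P %*% nrm) - sum(plane$origin * nrm), nrm)
  ia <- match(e_a, keys); ib <- match(e_b, keys)

  # chain segments (ia -> ib) through shared crossing-edge points
  nseg <- length(ia)
  adj <- vector("list", length(keys))
  for (s in seq_len(nseg)) {
    adj[[ia[s]]] <- c(adj[[ia[s]]], s)
    adj[[ib[s]]] <- c(adj[[ib[s]]], s)
  }
  used <- logical(nseg)
  out <- list()
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    chain <- walk_chain(s0, ia, ib, adj, used)
    closed <- chain$closed
    pts <- P[chain$nodes, , drop = FALSE]
    if (nrow(pts) >= if (closed) 3 else 2)
      out[[length(out) + 1]] <- polyline3d(pts, closed = closed)
  }
  out
}

walk_chain <- function(s0, ia, ib, adj, used) {
  env <- parent.frame()
  step_from <- function(seg, node) if (ia[seg] == node) ib[seg] else ia[seg]
  other_seg <- function(node, seg) {
    ss <- adj[[node]]
    ss <- ss[ss != seg & !env$used[ss]]
    if (length(ss)) ss[1] else 0L
  }
  # walk forward
  env$used[s0] <- TRUE
  start <- ia[s0]
  nodes <- c(start, step_from(s0, start))
  seg <- s0
  closed <- FALSE
  repeat {
    node <- nodes[length(nodes)]
    if (node == start) { closed <- TRUE; nodes <- nodes[-length(nodes)]; break }
    nxt <- other_seg(node, seg)
    if (nxt == 0L) break
    env$used[nxt] <- TRUE
    nodes <- c(nodes, step_from(nxt, node))
    seg <- nxt
  }
  if (!closed) {
    # walk backward from the start
    seg <- s0
    node <- start
    repeat {
      nxt <- other_seg(node, seg)
      if (nxt == 0L) break
      env$used[nxt] <- TRUE
      node <- step_from(nxt, node)
      nodes <- c(node, nodes)
      seg <- nxt
    }
  }
  list(nodes = nodes, closed = closed)
}
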
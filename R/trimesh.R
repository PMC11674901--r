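#' Triangle mesh in millimetres
#'
#' The universal geometry carrier of the package: an indexed triangle mesh
#' with an optional text label.  Faces with repeated vertex indices or zero
#' area are dropped at construction.
#'
#' @param vertices numeric matrix, one 3D point (mm) per row.
#' @param faces integer matrix, one triangle per row as 1-based vertex
#'   indices into `vertices`.
#' @param name text label carried through the pipeline.
#' @return an object of class `trimesh` with elements `vertices`, `faces`,
#'   `name`.
#' @export
trimesh <- function(vertices, faces, name = "") {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = NULL)
  faces <- matrix(as.integer(faces), ncol = 3, dimnames = NULL)
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    dup <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(dup)) faces <- faces[!dup, , drop = FALSE]
    a <- face_areas_internal(vertices, faces)
    if (any(a == 0)) faces <- faces[a > 0, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  wt <- tryCatch(is_watertight(x), error = function(e) NA)
  cat(sprintf("<trimesh '%s': %d vertices, %d faces, %s>\n", x$name,
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(wt)) "watertight" else "open"))
  invisible(x)
}

face_areas_internal <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [trimesh].
#' @return numeric scalar.
#' @export
mesh_area <- function(mesh) sum(face_areas_internal(mesh$vertices, mesh$faces))

#' Signed enclosed volume of a mesh (mm^3)
#'
#' Divergence-theorem volume; meaningful (and positive) for watertight
#' meshes with outward winding.
#' @param mesh a [trimesh].
#' @return numeric scalar.
#' @export
mesh_volume <- function(mesh) {
  cpp_mesh_volume(mesh$vertices, mesh$faces)
}

#' Per-face unit normals
#' @param mesh a [trimesh].
#' @return matrix with one unit normal per face.
#' @export
face_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-300)
}

#' Per-vertex normals (area-weighted face-normal average)
#' @param mesh a [trimesh].
#' @return matrix with one unit normal per vertex.
#' @export
vertex_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  # cross product magnitude = 2 * area, so unnormalised normals are already
  # area weighted
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  acc <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    acc[, 1] <- acc[, 1] + unname(tapply2(n[, 1], F[, k], nrow(V)))
    acc[, 2] <- acc[, 2] + unname(tapply2(n[, 2], F[, k], nrow(V)))
    acc[, 3] <- acc[, 3] + unname(tapply2(n[, 3], F[, k], nrow(V)))
  }
  len <- sqrt(rowSums(acc^2))
  acc / pmax(len, 1e-300)
}

tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

edge_key_internal <- function(a, b, n) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  (as.numeric(lo) - 1) * n + as.numeric(hi)
}

directed_edges_internal <- function(F) {
  rbind(cbind(F[, 1], F[, 2]), cbind(F[, 2], F[, 3]), cbind(F[, 3], F[, 1]))
}

#' Watertightness test
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces with opposite directions (consistent winding, no boundary).
#' @param mesh a [trimesh].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0) return(FALSE)
  de <- directed_edges_internal(F)
  n <- nrow(mesh$vertices)
  key <- sort(edge_key_internal(de[, 1], de[, 2], n))
  # every undirected edge exactly twice
  pair_ok <- length(key) %% 2 == 0 &&
    all(key[seq(1, length(key), 2)] == key[seq(2, length(key), 2)]) &&
    (length(key) < 4 ||
       !any(key[seq(2, length(key) - 1, 2)] == key[seq(3, length(key), 2)]))
  if (!pair_ok) return(FALSE)
  dkey <- sort((as.numeric(de[, 1]) - 1) * n + as.numeric(de[, 2]))
  # opposite direction once each: no directed edge repeated
  !any(dkey[-1] == dkey[-length(dkey)])
}

#' Boundary (naked) edges of a mesh
#' @param mesh a [trimesh].
#' @return two-column matrix of directed boundary edges (vertex indices).
#' @export
naked_edges <- function(mesh) {
  F <- mesh$faces
  de <- directed_edges_internal(F)
  n <- nrow(mesh$vertices)
  key <- edge_key_internal(de[, 1], de[, 2], n)
  o <- order(key)
  ks <- key[o]
  m <- length(ks)
  same_prev <- c(FALSE, ks[-1] == ks[-m])
  same_next <- c(same_prev[-1], FALSE)
  single <- o[!same_prev & !same_next]
  de[single, , drop = FALSE]
}

#' Boundary loops of an open mesh
#'
#' Chains the boundary edges (edges with exactly one incident face) into
#' closed polylines, following the face winding.  Watertight meshes return
#' an empty list.
#'
#' @param mesh a [trimesh] with consistent face winding.
#' @return list of closed [polyline3d] objects.
#' @export
naked_edge_loops <- function(mesh) {
  be <- naked_edges(mesh)
  if (nrow(be) == 0) return(list())
  # successor map: boundary edges follow winding, each start vertex once
  if (anyDuplicated(be[, 1]) || anyDuplicated(be[, 2])) {
    bad <- be[duplicated(be[, 1]) | duplicated(be[, 2]), , drop = FALSE]
    stop("boundary edges do not chain into closed loops (non-manifold); ",
         "offending edges: ",
         paste(apply(utils::head(bad, 5), 1, paste, collapse = "-"),
               collapse = ", "))
  }
  succ <- integer(nrow(mesh$vertices))
  succ[be[, 1]] <- be[, 2]
  visited <- logical(nrow(mesh$vertices))
  loops <- list()
  for (s in be[, 1]) {
    if (visited[s]) next
    cur <- s
    idx <- integer(0)
    repeat {
      idx <- c(idx, cur)
      visited[cur] <- TRUE
      cur <- succ[cur]
      if (cur == 0L) stop("boundary chain broken at vertex ", idx[length(idx)])
      if (cur == s) break
    }
    loops[[length(loops) + 1]] <-
      polyline3d(mesh$vertices[idx, , drop = FALSE], closed = TRUE)
  }
  loops
}

#' Concatenate meshes into one
#' @param ... [trimesh] objects.
#' @param name label for the result.
#' @return a [trimesh] holding all input triangles (indices re-based).
#' @export
merge_meshes <- function(..., name = "merged") {
  ms <- list(...)
  if (length(ms) == 1 && is.list(ms[[1]]) && !inherits(ms[[1]], "trimesh"))
    ms <- ms[[1]]
  V <- NULL; F <- NULL; off <- 0L
  for (m in ms) {
    V <- rbind(V, m$vertices)
    F <- rbind(F, m$faces + off)
    off <- off + nrow(m$vertices)
  }
  trimesh(V, F, name = name)
}

#' Merge coincident vertices
#' @param mesh a [trimesh].
#' @param tol welding tolerance (mm).
#' @return a [trimesh] with duplicate vertices merged.
#' @export
weld_vertices <- function(mesh, tol = 1e-9) {
  V <- mesh$vertices
  key <- paste(round(V[, 1] / tol), round(V[, 2] / tol), round(V[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  Vn <- V[first, , drop = FALSE]
  Fn <- matrix(map[mesh$faces], ncol = 3)
  trimesh(Vn, Fn, name = mesh$name)
}

#' Enforce consistent winding and outward orientation
#'
#' Flood-fills face orientation across shared edges and, for closed meshes,
#' flips the whole mesh if the signed volume is negative.
#' @param mesh a [trimesh].
#' @return a [trimesh] with consistent (outward, where closed) winding.
#' @export
orient_mesh <- function(mesh) {
  F <- mesh$faces
  nf <- nrow(F)
  if (nf == 0) return(mesh)
  n <- nrow(mesh$vertices)
  de <- directed_edges_internal(F)
  fid <- rep(seq_len(nf), 3)
  key <- edge_key_internal(de[, 1], de[, 2], n)
  o <- order(key)
  key_s <- key[o]; fid_s <- fid[o]
  dir_s <- de[o, 1] < de[o, 2]
  # adjacency between faces sharing an edge
  runs <- rle(key_s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  pair_a <- integer(0); pair_b <- integer(0); same_dir <- logical(0)
  two <- which(runs$lengths == 2)
  pair_a <- fid_s[starts[two]]
  pair_b <- fid_s[ends[two]]
  same_dir <- dir_s[starts[two]] == dir_s[ends[two]]
  adj <- vector("list", nf)
  for (i in seq_along(pair_a)) {
    adj[[pair_a[i]]] <- c(adj[[pair_a[i]]], i)
    adj[[pair_b[i]]] <- c(adj[[pair_b[i]]], i)
  }
  flip <- rep(NA, nf)
  queue <- integer(nf)
  for (seed in seq_len(nf)) {
    if (!is.na(flip[seed])) next
    flip[seed] <- FALSE
    queue[1] <- seed; qh <- 1L; qt <- 1L
    while (qh <= qt) {
      fcur <- queue[qh]; qh <- qh + 1L
      for (pi in adj[[fcur]]) {
        other <- if (pair_a[pi] == fcur) pair_b[pi] else pair_a[pi]
        # consistent winding means the shared edge runs in opposite
        # directions; same direction means one face needs flipping
        want <- if (same_dir[pi]) !flip[fcur] else flip[fcur]
        if (is.na(flip[other])) {
          flip[other] <- want
          qt <- qt + 1L
          queue[qt] <- other
        }
      }
    }
  }
  F2 <- F
  F2[flip, c(2, 3)] <- F[flip, c(3, 2)]
  out <- trimesh(mesh$vertices, F2, name = mesh$name)
  if (is_watertight(out) && mesh_volume(out) < 0)
    out$faces <- out$faces[, c(1, 3, 2)]
  out
}

bbox_internal <- function(mesh) {
  rbind(apply(mesh$vertices, 2, min), apply(mesh$vertices, 2, max))
}
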
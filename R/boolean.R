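#' Boolean operation on watertight meshes
#'
#' Primary path is an exact plane-splitting (BSP) Boolean whose output
#' vertices lie on the input surfaces, used for modest inputs; large or
#' near-coincident inputs are routed through a robust signed-distance voxel
#' remesh (marching tetrahedra) at `pitch` millimetres.  The BSP result is
#' welded and T-junction-repaired; if it still fails the watertightness
#' check the voxel path is used with a warning.
#'
#' @param a,b watertight [trimesh] inputs.
#' @param op `"union"`, `"difference"` (a minus b) or `"intersection"`.
#' @param method `"auto"`, `"bsp"` or `"voxel"`.
#' @param pitch voxel pitch (mm) for the voxel path; default 0.05, enlarged
#'   if the grid would exceed the cell budget.
#' @return a watertight [trimesh].
#' @export
mesh_boolean <- function(a, b, op = c("union", "difference", "intersection"),
                         method = c("auto", "bsp", "voxel"), pitch = NULL) {
  op <- match.arg(op)
  method <- match.arg(method)
  if (!is_watertight(a)) stop("mesh 'a' is not watertight")
  if (!is_watertight(b)) stop("mesh 'b' is not watertight")
  nf <- nrow(a$faces) + nrow(b$faces)
  if (method == "auto") method <- if (nf <= 2600) "bsp" else "voxel"
  name <- paste0(a$name, "_", substr(op, 1, 1), "_", b$name)
  if (method == "bsp") {
    opc <- match(op, c("union", "difference", "intersection")) - 1L
    res <- cpp_csg(a$vertices, a$faces, b$vertices, b$faces, opc)
    if (nrow(res$faces) == 0) {
      # empty result (e.g. disjoint intersection)
      return(trimesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3),
                     name = name))
    }
    m <- weld_vertices(trimesh(res$vertices, res$faces, name = name),
                       tol = 1e-7)
    m <- repair_tjunctions(m, tol = 1e-7)
    m <- orient_mesh(m)
    if (is_watertight(m)) return(m)
    warning("BSP Boolean produced a non-watertight mesh; ",
            "falling back to voxel remesh")
  }
  voxel_boolean(a, b, op, pitch = pitch, name = name)
}

voxel_boolean <- function(a, b, op, pitch = NULL, name = "bool",
                          max_cells = 2.5e7) {
  ba <- bbox_internal(a); bb <- bbox_internal(b)
  lo <- switch(op,
               union = pmin(ba[1, ], bb[1, ]),
               difference = ba[1, ],
               intersection = pmax(ba[1, ], bb[1, ]))
  hi <- switch(op,
               union = pmax(ba[2, ], bb[2, ]),
               difference = ba[2, ],
               intersection = pmin(ba[2, ], bb[2, ]))
  if (any(hi <= lo)) {
    if (op == "intersection")
      return(trimesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3),
                     name = name))
    stop("empty Boolean domain")
  }
  if (is.null(pitch)) pitch <- 0.05
  band <- 2L
  repeat {
    pad <- (band + 2) * pitch
    dims <- ceiling((hi - lo + 2 * pad) / pitch) + 1
    if (prod(dims) <= max_cells) break
    pitch <- pitch * 1.3
  }
  # irrational origin offset keeps grid columns off mesh vertices/edges
  origin <- lo - pad - pitch * c(0.2360679, 0.1415926, 0.1732050)
  fa <- cpp_sdf_grid(a$vertices, a$faces, origin, pitch, as.integer(dims),
                     band)
  fb <- cpp_sdf_grid(b$vertices, b$faces, origin, pitch, as.integer(dims),
                     band)
  fld <- switch(op,
                union = pmin(fa, fb),
                intersection = pmax(fa, fb),
                difference = pmax(fa, -fb))
  res <- cpp_marching_tetra(fld, origin, pitch, as.integer(dims))
  m <- trimesh(res$vertices, res$faces, name = name)
  m
}

# Remesh a single solid through the signed-distance / marching-tetrahedra
# path (used to robustify self-intersecting offsets).
voxel_remesh <- function(mesh, pitch = 0.05, max_cells = 2.5e7,
                         name = mesh$name) {
  bb <- bbox_internal(mesh)
  band <- 2L
  repeat {
    pad <- (band + 2) * pitch
    dims <- ceiling((bb[2, ] - bb[1, ] + 2 * pad) / pitch) + 1
    if (prod(dims) <= max_cells) break
    pitch <- pitch * 1.3
  }
  origin <- bb[1, ] - pad - pitch * c(0.2360679, 0.1415926, 0.1732050)
  f <- cpp_sdf_grid(mesh$vertices, mesh$faces, origin, pitch,
                    as.integer(dims), band)
  res <- cpp_marching_tetra(f, origin, pitch, as.integer(dims))
  trimesh(res$vertices, res$faces, name = name)
}

# Split faces whose boundary edge contains another boundary vertex in its
# interior (T junctions left by plane splitting).
repair_tjunctions <- function(mesh, tol = 1e-7, max_pass = 8) {
  for (pass in seq_len(max_pass)) {
    if (is_watertight(mesh)) return(mesh)
    ne <- naked_edges(mesh)
    if (nrow(ne) == 0) return(mesh)
    cand <- unique(as.integer(ne))
    V <- mesh$vertices
    F <- mesh$faces
    newF <- list()
    drop <- logical(nrow(F))
    nkey <- paste(pmin(ne[, 1], ne[, 2]), pmax(ne[, 1], ne[, 2]))
    changed <- FALSE
    for (fi in seq_len(nrow(F))) {
      tri <- F[fi, ]
      for (e in 1:3) {
        a <- tri[e]; b <- tri[if (e == 3) 1 else e + 1]
        if (!(paste(min(a, b), max(a, b)) %in% nkey)) next
        pa <- V[a, ]; pb <- V[b, ]
        ab <- sqrt(sum((pa - pb)^2))
        cc <- cand[cand != a & cand != b]
        if (!length(cc)) next
        da <- sqrt(rowSums((V[cc, , drop = FALSE] -
                              matrix(pa, length(cc), 3, byrow = TRUE))^2))
        db <- sqrt(rowSums((V[cc, , drop = FALSE] -
                              matrix(pb, length(cc), 3, byrow = TRUE))^2))
        onseg <- which(da + db - ab < tol & da > tol & db > tol)
        if (!length(onseg)) next
        vmid <- cc[onseg[which.min(da[onseg])]]
        c3 <- tri[if (e == 1) 3 else e - 1]
        newF[[length(newF) + 1]] <- rbind(c(a, vmid, c3), c(vmid, b, c3))
        drop[fi] <- TRUE
        changed <- TRUE
        break
      }
      if (drop[fi]) next
    }
    if (!changed) return(mesh)
    F2 <- rbind(F[!drop, , drop = FALSE], do.call(rbind, newF))
    mesh <- trimesh(V, F2, name = mesh$name)
  }
  mesh
}
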
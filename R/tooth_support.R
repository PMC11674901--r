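# Tooth-type support: cement shell, single-root premolar, two-root molar,
# periodontal-ligament shell.  All constructions keep exact vertex
# correspondence with the lumen so that mating surfaces are shared.

# ordered vertex indices of each boundary loop
naked_edge_loop_indices <- function(mesh) {
  be <- naked_edges(mesh)
  if (nrow(be) == 0) return(list())
  succ <- integer(nrow(mesh$vertices))
  succ[be[, 1]] <- be[, 2]
  visited <- logical(nrow(mesh$vertices))
  loops <- list()
  for (s in be[, 1]) {
    if (visited[s]) next
    cur <- s; idx <- integer(0)
    repeat {
      idx <- c(idx, cur); visited[cur] <- TRUE
      cur <- succ[cur]
      if (cur == 0L || cur == s) break
    }
    loops[[length(loops) + 1]] <- idx
  }
  loops
}

largest_loop_indices <- function(mesh) {
  loops <- naked_edge_loop_indices(mesh)
  if (length(loops) == 0) stop("mesh is closed: no boundary loop")
  lens <- vapply(loops, function(ix) {
    p <- mesh$vertices[ix, , drop = FALSE]
    sum(sqrt(rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2)))
  }, 1)
  loops[[which.max(lens)]]
}

#' Build the cement layer of one retainer
#'
#' Offsets the lumen surface into the cavity by the cement thickness
#' (keeping connectivity), lofts the two margin curves and joins lumen,
#' loft band and interior surface into a watertight shell.  The interior
#' surface and its margin curve are returned for the downstream abutment
#' construction.
#'
#' @param lumen open lumen [trimesh] with one margin loop.
#' @param d_cement cement thickness (mm), > 0.
#' @param side label used in part names.
#' @return list of class `cement_layer`: `cement` (watertight shell),
#'   `interior` (offset surface), `c_interior` (margin [polyline3d]),
#'   `interior_loop` (its vertex indices).
#' @export
make_cement_layer <- function(lumen, d_cement, side = "distal") {
  if (!is.numeric(d_cement) || d_cement <= 0)
    stop("d_cement must be > 0")
  loop <- largest_loop_indices(lumen)
  rim_centre <- colMeans(lumen$vertices[loop, , drop = FALSE])
  # offset into the cavity: pick the sign that moves the surface toward
  # the rim-loop centre (the cavity side of the cup)
  cand <- lapply(c("inward", "outward"), function(dir)
    suppressWarnings(offset_along_normals(lumen, d_cement, dir)))
  score <- vapply(cand, function(m)
    mean(sqrt(rowSums(sweep(m$vertices, 2, rim_centre)^2))), 1)
  interior <- cand[[which.min(score)]]
  # reject an offset that inverted faces (cement thicker than the local
  # curvature radius)
  fn0 <- face_normals(lumen); fn1 <- face_normals(interior)
  if (mean(rowSums(fn0 * fn1) < 0) > 0.001)
    stop("cement offset self-intersects (d_cement too large for this lumen)")
  interior$name <- paste0("interior_", side)
  A <- lumen$vertices[loop, , drop = FALSE]
  B <- interior$vertices[loop, , drop = FALSE]
  band <- strip_between(A, B, closed = TRUE, name = "margin_band")
  shell <- orient_mesh(weld_vertices(
    merge_meshes(list(lumen, band, interior),
                 name = paste0("cement_", side)), tol = 1e-9))
  if (!is_watertight(shell)) stop("cement shell failed to close")
  structure(list(cement = shell, interior = interior,
                 c_interior = polyline3d(B, closed = TRUE),
                 interior_loop = loop),
            class = "cement_layer")
}

root_level_curves <- function(c_interior_pts, params, d_tooth, side_centre) {
  z_min <- min(c_interior_pts[, 3])
  z_start <- z_min - params$epsilon
  n <- params$n_levels
  t <- seq(0, 1, length.out = n)
  sx <- bezier_value(params$bezier_x, t)
  sy <- bezier_value(params$bezier_y, t)
  if (any(sx <= 0) || any(sy <= 0))
    stop("Bezier scale profiles must stay positive")
  zs <- z_start - t * d_tooth
  ctr <- colMeans(c_interior_pts)
  curves <- vector("list", n)
  for (i in seq_len(n)) {
    # project the margin curve to the level plane, scale about its centroid
    p <- c_interior_pts
    p[, 1] <- ctr[1] + sx[i] * (p[, 1] - ctr[1])
    p[, 2] <- ctr[2] + sy[i] * (p[, 2] - ctr[2])
    p[, 3] <- zs[i]
    curves[[i]] <- p
  }
  list(curves = curves, t = t, z = zs, z_start = z_start,
       p_s = c(side_centre[1], side_centre[2], z_start))
}

# assemble dome (interior surface) + lateral loft + apex cap into one
# watertight tooth solid
assemble_root_solid <- function(interior, interior_loop, stack_curves, name) {
  mats <- c(list(interior$vertices[interior_loop, , drop = FALSE]),
            stack_curves)
  lateral <- loft_stack_exact(mats, closed = TRUE, name = "root_loft")
  K <- nrow(mats[[1]])
  apex <- stack_curves[[length(stack_curves)]]
  capV <- rbind(apex, colMeans(apex))
  ci <- nrow(capV)
  a <- seq_len(K); an <- c(a[-1], a[1])
  cap <- trimesh(capV, cbind(ci, a, an), name = "apex")
  solid <- orient_mesh(weld_vertices(
    merge_meshes(list(interior, lateral, cap), name = name), tol = 1e-9))
  if (!is_watertight(solid)) stop("root solid failed to close: ", name)
  solid
}

#' Build the single-root premolar abutment tooth
#'
#' Divides the root axis (length `d_tooth`, direction -z, starting
#' `epsilon` below the lowest margin point) into `n_levels` stations,
#' projects the interior margin curve to each level and scales it per axis
#' by the cubic Bezier value profiles, lofts through the stack and caps
#' the apex; the interior (cement-side) surface closes the solid.
#'
#' @param cem a `cement_layer` (see [make_cement_layer]).
#' @param params [tooth_params].
#' @param side_centre lumen landmark of this side (x, y used for the root
#'   start point).
#' @param name part name.
#' @return watertight [trimesh] with attributes `z_apex` and `z_start`.
#' @export
make_single_root <- function(cem, params, side_centre, name = "tooth_44") {
  pts <- cem$interior$vertices[cem$interior_loop, , drop = FALSE]
  lv <- root_level_curves(pts, params, params$d_tooth_premolar, side_centre)
  solid <- assemble_root_solid(cem$interior, cem$interior_loop, lv$curves,
                               name)
  attr(solid, "z_apex") <- lv$z[length(lv$z)]
  attr(solid, "z_start") <- lv$z_start
  attr(solid, "root_surface") <- root_surface_internal(cem, lv)
  solid
}

# open root surface (lateral loft + apex cap, open at the margin) used for
# the PDL construction
root_surface_internal <- function(cem, lv) {
  mats <- c(list(cem$interior$vertices[cem$interior_loop, , drop = FALSE]),
            lv$curves)
  lateral <- loft_stack_exact(mats, closed = TRUE, name = "root_surface")
  K <- nrow(mats[[1]])
  apex <- lv$curves[[length(lv$curves)]]
  capV <- rbind(apex, colMeans(apex))
  ci <- nrow(capV)
  a <- seq_len(K); an <- c(a[-1], a[1])
  cap <- trimesh(capV, cbind(ci, a, an), name = "apex")
  weld_vertices(merge_meshes(list(lateral, cap), name = "root_surface"),
                tol = 1e-9)
}

#' Build the two-root molar abutment tooth
#'
#' As [make_single_root], but the level curves are duplicated and
#' translated by `+-B_T(t) * d_r` in x (the translation Bezier starts at 0,
#' so the roots share the cervical portion and separate toward the apex);
#' the two rooted solids are merged by a Boolean union.
#'
#' @param cem a `cement_layer`.
#' @param params [tooth_params].
#' @param side_centre lumen landmark of this side.
#' @param name part name.
#' @param pitch voxel pitch for the union (mm).
#' @return watertight [trimesh] with attributes `z_apex`, `z_start`,
#'   `root_solids` (the two pre-union solids).
#' @export
make_two_root <- function(cem, params, side_centre, name = "tooth_47",
                          pitch = 0.08) {
  pts <- cem$interior$vertices[cem$interior_loop, , drop = FALSE]
  lv <- root_level_curves(pts, params, params$d_tooth_molar, side_centre)
  bt <- bezier_value(params$bezier_t, lv$t)
  shift <- bt * params$d_r
  curves1 <- lapply(seq_along(lv$curves), function(i) {
    p <- lv$curves[[i]]; p[, 1] <- p[, 1] + shift[i]; p
  })
  curves2 <- lapply(seq_along(lv$curves), function(i) {
    p <- lv$curves[[i]]; p[, 1] <- p[, 1] - shift[i]; p
  })
  s1 <- assemble_root_solid(cem$interior, cem$interior_loop, curves1,
                            paste0(name, "_r1"))
  s2 <- assemble_root_solid(cem$interior, cem$interior_loop, curves2,
                            paste0(name, "_r2"))
  u <- mesh_boolean(s1, s2, "union", method = "voxel", pitch = pitch)
  u$name <- name
  if (!is_watertight(u)) stop("molar union failed")
  attr(u, "z_apex") <- lv$z[length(lv$z)]
  attr(u, "z_start") <- lv$z_start
  attr(u, "root_solids") <- list(s1, s2)
  lvs <- lv
  attr(u, "root_surfaces") <- list(
    root_surface_internal(cem, within_shift(lvs, shift)),
    root_surface_internal(cem, within_shift(lvs, -shift)))
  u
}

within_shift <- function(lv, shift) {
  lv$curves <- lapply(seq_along(lv$curves), function(i) {
    p <- lv$curves[[i]]; p[, 1] <- p[, 1] + shift[i]; p
  })
  lv
}

#' Build a periodontal-ligament shell around a root surface
#'
#' Offsets the open root surface (lateral loft + apex, open at the
#' cervical margin) outward along its vertex normals by `d_pdl`, lofts the
#' two margin loops and closes the shell.
#'
#' @param root_surface open [trimesh] (e.g. attribute `root_surface` of
#'   [make_single_root]).
#' @param d_pdl ligament thickness (mm).
#' @param name part name.
#' @return watertight [trimesh] shell of mean thickness `d_pdl`.
#' @export
make_pdl <- function(root_surface, d_pdl, name = "pdl") {
  if (!is.numeric(d_pdl) || d_pdl <= 0) stop("d_pdl must be > 0")
  loop <- largest_loop_indices(root_surface)
  ctr <- colMeans(root_surface$vertices)
  cand <- lapply(c("inward", "outward"), function(dir)
    suppressWarnings(offset_along_normals(root_surface, d_pdl, dir)))
  score <- vapply(cand, function(m)
    mean(sqrt(rowSums(sweep(m$vertices, 2, ctr)^2))), 1)
  outer <- cand[[which.max(score)]]     # outward: away from the root
  A <- root_surface$vertices[loop, , drop = FALSE]
  B <- outer$vertices[loop, , drop = FALSE]
  band <- strip_between(A, B, closed = TRUE, name = "pdl_band")
  shell <- orient_mesh(weld_vertices(
    merge_meshes(list(root_surface, band, outer), name = name), tol = 1e-9))
  if (!is_watertight(shell)) stop("PDL shell failed to close")
  shell
}

# molar PDL: shell of the union of the two root solids, built through the
# signed-distance field (dilation minus solid, cut at the cervical level)
make_pdl_molar <- function(root_solids, d_pdl, z_top, pitch = 0.09,
                           name = "pdl_47") {
  s1 <- root_solids[[1]]; s2 <- root_solids[[2]]
  lo <- pmin(bbox_internal(s1)[1, ], bbox_internal(s2)[1, ]) - d_pdl
  hi <- pmax(bbox_internal(s1)[2, ], bbox_internal(s2)[2, ]) + d_pdl
  hi[3] <- min(hi[3], z_top + 4 * pitch)   # everything above the cut is waste
  band <- as.integer(ceiling(d_pdl / pitch) + 2)
  pad <- (band + 2) * pitch
  dims <- as.integer(ceiling((hi - lo + 2 * pad) / pitch) + 1)
  origin <- lo - pad - pitch * c(0.2360679, 0.1415926, 0.1732050)
  f1 <- cpp_sdf_grid(s1$vertices, s1$faces, origin, pitch, dims, band)
  f2 <- cpp_sdf_grid(s2$vertices, s2$faces, origin, pitch, dims, band)
  fu <- pmin(f1, f2)
  zs <- origin[3] + (seq_len(dims[3]) - 1) * pitch
  zfield <- rep(zs, each = dims[1] * dims[2])
  shell <- pmax(fu - d_pdl, -fu, zfield - z_top)
  res <- cpp_marching_tetra(shell, origin, pitch, dims)
  m <- trimesh(res$vertices, res$faces, name = name)
  if (!is_watertight(m)) stop("molar PDL shell failed to close")
  m
}

#' Generate the complete tooth-type support for an aligned FPD
#'
#' Cement layers on both sides, single-root premolar on the mesial side,
#' two-root molar on the distal side, and the periodontal-ligament shells.
#'
#' @param aligned result of [align_fpd] (or an aligned [fpd_model] plus
#'   landmarks).
#' @param params [tooth_params].
#' @return named list of watertight parts: `cement_distal`,
#'   `cement_mesial`, `tooth_47`, `tooth_44`, `pdl_47`, `pdl_44`.
#' @export
generate_tooth_support <- function(aligned, params = tooth_params()) {
  fpd <- aligned$fpd; lm <- aligned$landmarks
  cem_d <- make_cement_layer(fpd$distal, params$d_cement, "distal")
  cem_m <- make_cement_layer(fpd$mesial, params$d_cement, "mesial")
  molar <- make_two_root(cem_d, params, lm$p_distal, name = "tooth_47")
  premolar <- make_single_root(cem_m, params, lm$p_mesial, name = "tooth_44")
  pdl_44 <- make_pdl(attr(premolar, "root_surface"), params$d_pdl,
                     name = "pdl_44")
  pdl_47 <- make_pdl_molar(attr(molar, "root_solids"), params$d_pdl,
                           z_top = attr(molar, "z_start"), name = "pdl_47")
  list(cement_distal = cem_d$cement, cement_mesial = cem_m$cement,
       tooth_47 = molar, tooth_44 = premolar,
       pdl_47 = pdl_47, pdl_44 = pdl_44)
}
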
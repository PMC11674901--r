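# Insertion of the restoration into the mandibular segment, Boolean
# subtraction of the support cavity, saucer-shaped crestal defect carving
# and trimming of the periodontal ligament to the bone domain.

#' Saucer defect specification
#'
#' Circular-arc vertical profile of maximal depth `depth` spanning
#' `width` mesiodistally, covering the full buccal-oral width, with
#' `fillet_radius` corner rounding where the saucer meets the intact
#' crest.
#'
#' @param depth maximal bone-loss depth (mm), in `[0, 3]` in the study.
#' @param width mesiodistal defect width (mm).
#' @param fillet_radius rim fillet (mm).
#' @param sites x positions (bone frame) of the support centres.
#' @return list of class `defect_spec`.
#' @export
defect_spec <- function(depth, width = 10, fillet_radius = 0.4,
                        sites = numeric(0)) {
  if (depth < 0) stop("defect depth must be >= 0")
  if (width <= 0) stop("defect width must be > 0")
  structure(list(depth = depth, width = width,
                 fillet_radius = fillet_radius, shape = "saucer",
                 sites = sites), class = "defect_spec")
}

# vertical drop of the saucer profile at mesiodistal offset u from the
# site centre; arc through (-w/2, 0), (0, -depth), (w/2, 0) with rim
# fillets appended outside the corners
saucer_drop <- function(u, depth, width, rf) {
  if (depth <= 0) return(rep(0, length(u)))
  w2 <- width / 2
  R <- (depth^2 + w2^2) / (2 * depth)
  cz <- R - depth                       # arc centre height above the crest
  # fillet circle: tangent to the crest line and externally to the arc
  xt <- sqrt((R + rf)^2 - (cz + rf)^2)  # tangency point on the crest
  uj <- xt * R / (R + rf)               # arc/fillet joint
  au <- abs(u)
  drop <- numeric(length(u))
  inarc <- au <= uj
  drop[inarc] <- pmax(0, -(cz - sqrt(pmax(0, R^2 - au[inarc]^2))))
  infil <- au > uj & au < xt
  drop[infil] <- rf - sqrt(pmax(0, rf^2 - (au[infil] - xt)^2))
  drop
}

crest_height_fun <- function(bone) {
  # z of the (possibly defected) crestal surface as a function of x
  d <- bone$defect
  function(x) {
    z <- rep(bone$crest_z, length(x))
    if (!is.null(d) && d$depth > 0) {
      for (s in d$sites)
        z <- pmin(z, bone$crest_z - saucer_drop(x - s, d$depth, d$width,
                                                d$fillet_radius))
    }
    z
  }
}

#' Build the bone local frame for insertion
#'
#' Marks two points on the mandibular centre curve at arc distance `span`
#' (centred on the curve), projects them up to the crestal surface, and
#' builds the right-handed frame: origin at the projected distal point,
#' z along the projection direction, x toward the mesial point.
#'
#' @param bone a `bone_segment`.
#' @param span mesiodistal distance between the FPD lumen centres (mm).
#' @return list with `frame` ([frame3d]), the curve points and their
#'   crestal projections.
#' @export
build_bone_frame <- function(bone, span) {
  cm <- bone$centre_curve
  L <- polyline_length(cm)
  if (span >= L) stop("span exceeds the centre-curve length")
  s0 <- (L - span) / 2
  rs <- resample_polyline(cm, 257)$points
  svals <- seq(0, L, length.out = 257)
  pick <- function(s) {
    i <- which.min(abs(svals - s))
    rs[i, ]
  }
  p_cm_d <- pick(s0); p_cm_m <- pick(s0 + span)
  ch <- crest_height_fun(bone)
  p_d <- c(p_cm_d[1], p_cm_d[2], ch(p_cm_d[1]))
  p_m <- c(p_cm_m[1], p_cm_m[2], ch(p_cm_m[1]))
  up <- c(0, 0, 1)
  fr <- frame_from_zx(p_d, up, p_m - p_d)
  list(frame = fr, p_cm_distal = p_cm_d, p_cm_mesial = p_cm_m,
       p_distal = p_d, p_mesial = p_m)
}

#' Place the restoration assembly over the bone
#'
#' Applies one rigid motion to every part (FPD frame onto bone frame) and
#' then lifts the assembly by `d_bone` along the bone vertical, so the
#' distal lumen centre sits `d_bone` above the crestal surface.
#'
#' @param assembly named list of [trimesh] parts in the aligned FPD frame.
#' @param fpd_frame the assembly frame (global identity after
#'   [align_fpd]).
#' @param bone_frame result of [build_bone_frame] (or a [frame3d]).
#' @param d_bone gap between the distal lumen centre and the crest (mm).
#' @param bone the `bone_segment` (for the reach check).
#' @return named list of transformed parts.
#' @export
place_assembly <- function(assembly, fpd_frame = frame3d(), bone_frame,
                           d_bone = 2.8, bone = NULL) {
  if (!inherits(bone_frame, "frame3d")) bone_frame <- bone_frame$frame
  target <- frame3d(bone_frame$origin + d_bone * bone_frame$axes[3, ],
                    bone_frame$axes)
  placed <- lapply(assembly, transform_to_frame, from = fpd_frame,
                   to = target)
  if (!is.null(bone)) {
    lows <- vapply(placed, function(m) min(m$vertices[, 3]), 1)
    if (min(lows) > bone$crest_z)
      stop("supports do not reach the bone (d_bone too large)")
  }
  placed
}

#' Subtract the placed support parts from the bone
#'
#' Boolean difference of the bone solid and the union of the given parts
#' (tooth supports: the PDL shells bound the cavity; implant supports: the
#' implant bodies), through the signed-distance voxel path.
#'
#' @param bone a `bone_segment`.
#' @param parts list of placed watertight [trimesh] parts to subtract.
#' @param pitch voxel pitch (mm).
#' @return the `bone_segment` with its outer solid replaced.
#' @export
subtract_assembly <- function(bone, parts, pitch = 0.1) {
  for (p in parts) if (!is_watertight(p))
    stop("part '", p$name, "' is not watertight")
  bb <- bbox_internal(bone$outer)
  band <- 2L
  pad <- (band + 2) * pitch
  dims <- as.integer(ceiling((bb[2, ] - bb[1, ] + 2 * pad) / pitch) + 1)
  origin <- bb[1, ] - pad - pitch * c(0.2360679, 0.1415926, 0.1732050)
  fb <- cpp_sdf_grid(bone$outer$vertices, bone$outer$faces, origin, pitch,
                     dims, band)
  inter <- FALSE
  for (p in parts) {
    pb <- bbox_internal(p)
    if (any(pb[1, ] > bb[2, ]) || any(pb[2, ] < bb[1, ])) next
    fp <- cpp_sdf_grid(p$vertices, p$faces, origin, pitch, dims, band)
    fb <- pmax(fb, -fp)
    inter <- TRUE
  }
  if (!inter) return(bone)
  res <- cpp_marching_tetra(fb, origin, pitch, dims)
  out <- trimesh(res$vertices, res$faces, name = bone$outer$name)
  if (!is_watertight(out)) stop("bone subtraction failed to close")
  bone$outer <- out
  bone
}

#' Carve saucer-shaped crestal defects
#'
#' Clips the bone solid against the defected crest surface
#' z = crest - drop(x): every vertex above the cut is projected down onto
#' it.  Exact identity at depth 0 and idempotent under an equal spec.
#'
#' @param bone a `bone_segment`.
#' @param spec a [defect_spec]; its `sites` must lie on the crest.
#' @return the `bone_segment` with the defect applied and recorded.
#' @export
carve_defect <- function(bone, spec) {
  if (length(spec$sites) == 0) stop("defect spec has no sites")
  if (spec$depth > bone$cortical_thickness + bone$transition_thickness)
    warning("defect reaches into the cancellous layer")
  if (spec$depth > 0) {
    V <- bone$outer$vertices
    drop <- rep(0, nrow(V))
    for (s in spec$sites)
      drop <- pmax(drop, saucer_drop(V[, 1] - s, spec$depth, spec$width,
                                     spec$fillet_radius))
    zcut <- bone$crest_z - drop
    V[, 3] <- pmin(V[, 3], zcut)
    # assign in place: faces flattened onto the cut surface may become
    # zero-area, but removing them would open the mesh
    bone$outer$vertices <- V
  }
  bone$defect <- spec
  bone
}

#' Trim the periodontal ligament to the bone domain
#'
#' Intersects the PDL shell with the half-space below the (possibly
#' defected) crestal surface, so only the ligament in contact with bone
#' remains.
#'
#' @param pdl placed watertight PDL [trimesh].
#' @param bone the post-defect `bone_segment`.
#' @param pitch voxel pitch (mm).
#' @return watertight trimmed [trimesh].
#' @export
trim_pdl <- function(pdl, bone, pitch = 0.05) {
  ch <- crest_height_fun(bone)
  bb <- bbox_internal(pdl)
  if (bb[1, 3] > bone$crest_z)
    stop("PDL lies entirely above the bone: nothing remains after trimming")
  bb[2, 3] <- min(bb[2, 3], bone$crest_z + 2 * pitch)
  band <- 2L
  pad <- (band + 2) * pitch
  dims <- as.integer(ceiling((bb[2, ] - bb[1, ] + 2 * pad) / pitch) + 1)
  origin <- bb[1, ] - pad - pitch * c(0.2360679, 0.1415926, 0.1732050)
  fp <- cpp_sdf_grid(pdl$vertices, pdl$faces, origin, pitch, dims, band)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * pitch
  zs <- origin[3] + (seq_len(dims[3]) - 1) * pitch
  crest_x <- ch(xs)
  # field of the cut half-space z <= crest(x)
  cut <- rep(zs, each = dims[1] * dims[2]) -
    rep(crest_x, times = dims[2] * dims[3])
  res <- cpp_marching_tetra(pmax(fp, cut), origin, pitch, dims)
  out <- trimesh(res$vertices, res$faces, name = paste0(pdl$name, "_trim"))
  if (nrow(out$faces) == 0)
    stop("PDL lies entirely above the bone: nothing remains after trimming")
  if (!is_watertight(out)) stop("PDL trim failed to close")
  out
}
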
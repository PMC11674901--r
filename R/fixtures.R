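# Deterministic synthetic fixtures: labeled FPD models (tooth-like and
# implant-like lumens) and a layered mandibular bone segment.  These
# emulate the scanned master geometry the pipeline was designed for; all
# randomness flows through one seeded generator and construction ground
# truth is recorded for tests.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

# open lumen cup: rim at z ~ 0, dome rising to `depth`; g(theta) shapes the
# cross-section, wave(theta) the rim height
lumen_cup <- function(centre_xy, r0, depth, g, wave, n_theta = 128,
                      n_levels = 20, name = "lumen") {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  gv <- g(th)
  wv <- wave(th)
  s <- seq(0, 1, length.out = n_levels + 1)
  rows <- vector("list", n_levels + 1)
  for (i in seq_along(s)) {
    si <- s[i]
    taper <- 1 - 0.28 * si
    cap <- if (si > 0.7) sqrt(pmax(0, 1 - ((si - 0.7) / 0.3)^2)) else 1
    rr <- r0 * gv * taper * cap
    zz <- depth * si + wv * (1 - si)
    rows[[i]] <- cbind(centre_xy[1] + rr * cos(th),
                       centre_xy[2] + rr * sin(th), zz)
  }
  # grid faces; last row collapses to the pole
  V <- do.call(rbind, rows[seq_len(n_levels)])
  pole <- c(centre_xy[1], centre_xy[2], depth)
  V <- rbind(V, pole)
  K <- n_theta
  F <- NULL
  for (lev in seq_len(n_levels - 1)) {
    a <- (lev - 1) * K + seq_len(K)
    b <- lev * K + seq_len(K)
    an <- c(a[-1], a[1]); bn <- c(b[-1], b[1])
    F <- rbind(F, cbind(a, bn, b), cbind(a, an, bn))
  }
  a <- (n_levels - 1) * K + seq_len(K)
  an <- c(a[-1], a[1])
  pi_ <- nrow(V)
  F <- rbind(F, cbind(a, an, pi_))
  trimesh(V, F, name = name)
}

loaf_surface <- function(span, lumen_info, n_u = 72, n_v = 40) {
  # deep ellipsoid clamped at z = -0.2: the clamp produces a genuinely
  # flat gingival facet that pins the bounding-box / gingival-plane
  # detection
  centre <- c(span / 2, 0, 3.7)
  semi <- c(span / 2 + 7, 5.5, 4.8)
  u <- seq(0, 2 * pi, length.out = n_u + 1)[-(n_u + 1)]
  v <- seq(0, pi, length.out = n_v + 1)
  s <- sphere_mesh(centre = c(0, 0, 0), radius = 1, n_theta = n_u,
                   n_phi = n_v, name = "surface")
  V <- sweep(s$vertices %*% diag(semi), 2, -centre)
  V[, 3] <- pmax(V[, 3], -0.2)     # flat gingival underside
  m <- trimesh(V, s$faces, name = "surface")
  # open margin windows under each lumen
  cen <- (V[m$faces[, 1], ] + V[m$faces[, 2], ] + V[m$faces[, 3], ]) / 3
  drop <- rep(FALSE, nrow(m$faces))
  for (li in lumen_info) {
    d2 <- (cen[, 1] - li$centre[1])^2 + (cen[, 2] - li$centre[2])^2
    drop <- drop | (cen[, 3] < 0.1 & d2 < (0.8 * li$r0)^2)
  }
  trimesh(m$vertices, m$faces[!drop, , drop = FALSE], name = "surface")
}

random_rotation <- function() {
  # uniform rotation via quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Generate a synthetic labeled FPD
#'
#' Builds a 4-unit bridge with two open lumens at `lumen_span` mm spacing:
#' implant-type lumens are low-noise surfaces of revolution (near-circular
#' sections, CI >= 0.99), tooth-type lumens carry two- and four-lobed
#' harmonics that land the circularity index in the published tooth regime
#' (about 0.92).  The model is returned in a random rigid pose drawn from
#' the seed, together with the construction ground truth.
#'
#' @param support_type `"tooth"` or `"implant"`.
#' @param seed integer seed; identical seeds give identical output.
#' @param lumen_span mesiodistal distance between the lumen centres (mm).
#' @param lumen_depth lumen dome height (mm); defaults 4.5 (tooth) / 3.0
#'   (implant).
#' @param noise_amplitude relative radial noise; defaults 0.01 (tooth) /
#'   0.002 (implant).
#' @param pose apply a random rigid pose (FALSE returns the construction
#'   pose: distal margin centre near the origin, +z occlusal).
#' @return list with `fpd` (an [fpd_model]) and `truth` (recorded
#'   landmarks, pose and expected CI band).
#' @export
make_fpd_fixture <- function(support_type = c("tooth", "implant"), seed = 0,
                             lumen_span = 30, lumen_depth = NULL,
                             noise_amplitude = NULL, pose = TRUE) {
  support_type <- match.arg(support_type)
  if (is.null(lumen_depth))
    lumen_depth <- if (support_type == "tooth") 4.5 else 3.0
  if (is.null(noise_amplitude))
    noise_amplitude <- if (support_type == "tooth") 0.01 else 0.002
  with_seed(seed, {
    mk_g <- function() {
      ks <- 5:8
      amp <- stats::runif(length(ks), 0, noise_amplitude)
      ph <- stats::runif(length(ks), 0, 2 * pi)
      base <- if (support_type == "tooth") {
        function(th) 1 + 0.22 * cos(2 * th) + 0.07 * cos(4 * th)
      } else {
        function(th) rep(1, length(th))
      }
      function(th) {
        out <- base(th)
        for (i in seq_along(ks)) out <- out + amp[i] * cos(ks[i] * th + ph[i])
        out
      }
    }
    mk_wave <- function() {
      if (support_type == "tooth") {
        ph <- stats::runif(1, 0, 2 * pi)
        function(th) 0.3 * cos(2 * th + ph)
      } else function(th) rep(0, length(th))
    }
    r0_distal <- if (support_type == "tooth") 4.0 else 2.4
    r0_mesial <- if (support_type == "tooth") 3.0 else 2.4
    g_d <- mk_g(); g_m <- mk_g()
    w_d <- mk_wave(); w_m <- mk_wave()
    distal <- lumen_cup(c(0, 0), r0_distal, lumen_depth, g_d, w_d,
                        name = "distal")
    mesial <- lumen_cup(c(lumen_span, 0), r0_mesial, lumen_depth, g_m, w_m,
                        name = "mesial")
    surface <- loaf_surface(lumen_span,
                            list(list(centre = c(0, 0), r0 = r0_distal),
                                 list(centre = c(lumen_span, 0),
                                      r0 = r0_mesial)))
    fpd0 <- fpd_model(surface, distal, mesial)
    lm0 <- extract_landmarks(fpd0)
    R <- diag(3); tr <- c(0, 0, 0)
    if (pose) {
      R <- random_rotation()
      tr <- stats::runif(3, -40, 40)
    }
    fpd <- fpd_model(apply_rigid(surface, R, tr), apply_rigid(distal, R, tr),
                     apply_rigid(mesial, R, tr))
    truth <- list(
      support_type = support_type,
      seed = seed,
      lumen_span = lumen_span,
      p_distal = as.numeric(R %*% lm0$p_distal) + tr,
      p_mesial = as.numeric(R %*% lm0$p_mesial) + tr,
      p_distal_local = lm0$p_distal,
      p_mesial_local = lm0$p_mesial,
      gingival_normal = as.numeric(R %*% c(0, 0, -1)),
      rotation = R, translation = tr,
      r0 = c(distal = r0_distal, mesial = r0_mesial),
      lumen_depth = lumen_depth,
      ci_band = if (support_type == "tooth") c(0.88, 0.95) else c(0.99, 1))
    list(fpd = fpd, truth = truth)
  })
}

# --- bone fixture -----------------------------------------------------------

# Cross-section profile in (y, z): flat crest at z = 0, filleted crest
# corners, outward-sloping flanks, rounded flat base.  The path is an
# arc-spline (lines + tangent arcs), so `inset` -- shrink arc radii, shift
# lines inward -- is an exact constant-distance inward offset, which is how
# the nested layer interfaces are built.
bone_profile <- function(inset = 0, crest_half = 4.5, height = 18,
                         flank_lean = 0.08, r_crest = 3.5, r_base = 3.0,
                         step = 0.15) {
  m <- inset
  if (r_crest - m <= 0.05 || r_base - m <= 0.05)
    stop("inset exceeds profile fillet radii")
  phi <- atan(flank_lean)                 # outward lean of the flanks
  nrm <- c(cos(phi), sin(phi))            # outward normal of the right flank
  alpha <- phi                            # polar angle of nrm
  # crest corner arc: tangent to z = 0 at y = crest_half, tangent to flank
  c1 <- c(crest_half, -r_crest)
  cline <- sum(nrm * c1) + r_crest        # flank line: nrm . p = cline
  # base corner arc: tangent to z = -height and to the flank line
  c2z <- -height + r_base
  c2y <- (cline - r_base - nrm[2] * c2z) / nrm[1]
  c2 <- c(c2y, c2z)
  arc_pts <- function(cen, r, from, to) {
    np <- max(3, ceiling(abs(to - from) * r / step))
    ang <- seq(from, to, length.out = np)
    cbind(cen[1] + r * cos(ang), cen[2] + r * sin(ang))
  }
  crest_pts <- cbind(seq(0, crest_half, by = step), -m)
  arc1 <- arc_pts(c1, r_crest - m, pi / 2, alpha)
  f_from <- c1 + (r_crest - m) * nrm
  f_to <- c2 + (r_base - m) * nrm
  nfl <- max(3, ceiling(sqrt(sum((f_to - f_from)^2)) / (3 * step)))
  flank_pts <- cbind(seq(f_from[1], f_to[1], length.out = nfl),
                     seq(f_from[2], f_to[2], length.out = nfl))
  arc2 <- arc_pts(c2, r_base - m, alpha, -pi / 2)
  base_pts <- cbind(seq(c2[1], 0, length.out = max(3, ceiling(c2[1] /
                                                     (3 * step)))),
                    -height + m)
  right <- rbind(crest_pts, arc1[-1, , drop = FALSE],
                 flank_pts[-1, , drop = FALSE], arc2[-1, , drop = FALSE],
                 base_pts[-1, , drop = FALSE])
  left <- right[rev(seq_len(nrow(right))), , drop = FALSE]
  left <- left[-c(1, nrow(left)), , drop = FALSE]
  left[, 1] <- -left[, 1]
  rbind(right, left)
}

extrude_profile <- function(prof, xs, name = "bone") {
  K <- nrow(prof)
  rows <- lapply(xs, function(x) cbind(x, prof[, 1], prof[, 2]))
  solid_from_sections(rows, name = name, cap_first = TRUE, cap_last = TRUE)
}

#' Generate a synthetic layered mandibular bone segment
#'
#' Extruded arc-spline cross-section (flat crest, filleted corners,
#' outward-sloping flanks) with the cortical and transition-layer
#' interfaces built as exact inward offsets of the outer surface; layer
#' thicknesses follow the requested Misch quality (0.29 mm transition).
#' The crest is straight, carries the centre curve, and is meshed finely
#' enough for defect carving.
#'
#' @param quality Misch quality `"D1"`..`"D4"`.
#' @param seed integer seed (kept for interface symmetry; the segment is
#'   fully deterministic).
#' @param length mesiodistal extent (mm).
#' @param crest_half buccal-oral half-width of the flat crest (mm).
#' @param height total segment height (mm).
#' @param x_step extrusion sampling along the ridge (mm).
#' @return object of class `bone_segment`.
#' @export
make_bone_fixture <- function(quality = "D1", seed = 0, length = 48,
                              crest_half = 4.5, height = 18, x_step = 0.15) {
  spec <- bone_quality(quality)
  prof0 <- bone_profile(0, crest_half = crest_half, height = height)
  prof1 <- bone_profile(spec$cortical_thickness, crest_half = crest_half,
                        height = height)
  prof2 <- bone_profile(spec$cortical_thickness + spec$transition_thickness,
                        crest_half = crest_half, height = height)
  xs0 <- seq(0, length, by = x_step)
  t1 <- spec$cortical_thickness
  t2 <- t1 + spec$transition_thickness
  xs1 <- seq(t1, length - t1, by = 4 * x_step)
  xs2 <- seq(t2, length - t2, by = 4 * x_step)
  outer <- extrude_profile(prof0, xs0, name = "bone")
  cort <- extrude_profile(prof1, xs1, name = "cortical_interface")
  trans <- extrude_profile(prof2, xs2, name = "transition_interface")
  cm <- polyline3d(cbind(seq(0, length, length.out = 97), 0, 0),
                   closed = FALSE)
  structure(list(outer = outer, cortical_interface = cort,
                 transition_interface = trans, centre_curve = cm,
                 quality = spec$label,
                 cortical_thickness = spec$cortical_thickness,
                 transition_thickness = spec$transition_thickness,
                 crest_half = crest_half, length = length, height = height,
                 crest_z = 0, defect = NULL),
            class = "bone_segment")
}

#' @export
print.bone_segment <- function(x, ...) {
  cat(sprintf("<bone_segment %s: %.0f mm ridge, cortical %.1f mm%s>\n",
              x$quality, x$length, x$cortical_thickness,
              if (!is.null(x$defect))
                sprintf(", defect depth %.1f mm", x$defect$depth) else ""))
  invisible(x)
}
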
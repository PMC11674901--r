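# Implant-type support: abutment loft with stepped access bore, implant
# body with chamfered bore opening, apex fillet and helical V-thread,
# abutment screw.  The implant and screw are bodies of revolution built as
# radial height-fields, which keeps them exactly watertight; the thread is
# an analytic V-groove in the height-field, identical by construction to
# sweeping the metric profile along the helix and subtracting.

ring_at <- function(theta, r, z) cbind(r * cos(theta), r * sin(theta), z)

revolve_profile <- function(rz, n_theta = 96, centre_xy = c(0, 0),
                            name = "rev") {
  # rz: matrix (r, z) from top cap to bottom cap; r > 0 in the interior,
  # first/last rows may have r = 0 (poles) else flat fan caps are added
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  rings <- lapply(seq_len(nrow(rz)), function(i)
    cbind(centre_xy[1] + rz[i, 1] * cos(th), centre_xy[2] + rz[i, 1] * sin(th),
          rz[i, 2]))
  solid_from_sections(rings, name = name, cap_first = TRUE, cap_last = TRUE)
}

abutment_geometry <- function(cem, p) {
  pts <- cem$interior$vertices[cem$interior_loop, , drop = FALSE]
  z_min <- min(pts[, 3])
  ctr <- colMeans(pts)
  z_apex <- max(cem$interior$vertices[, 3])
  list(pts = pts, z_min = z_min, centre_xy = ctr[1:2],
       z_neck = z_min - p$l_a1,
       z_a2 = z_min - p$l_a2,
       z_bottom = z_apex - p$l_a3,
       z_apex = z_apex)
}

#' Build the implant abutment
#'
#' Lofts the interior margin curve through three circles (the taper to the
#' implant neck plane and the cylindrical post) with the cement-side dome
#' closing the top, and carves the stepped screw-access bore (upper bore
#' reaching the cement layer, conical screw seat, through-bore to the
#' bottom face).  All rings share the angular parametrisation of the
#' margin curve, so the solid closes exactly.
#'
#' @param cem a `cement_layer` of the implant-variant lumen.
#' @param p [implant_params].
#' @param side label for part naming.
#' @return watertight [trimesh] with attribute `geom` (axial datums used
#'   downstream by implant and screw).
#' @export
make_abutment <- function(cem, p, side = "distal") {
  g <- abutment_geometry(cem, p)
  pts <- g$pts
  # angular order of the margin points around the abutment axis
  th <- atan2(pts[, 2] - g$centre_xy[2], pts[, 1] - g$centre_xy[1])
  # the margin curve must wind once around the axis for the ring
  # correspondence to be twist-free
  winding <- sum(((diff(c(th, th[1])) + pi) %% (2 * pi)) - pi)
  if (abs(abs(winding) - 2 * pi) > 0.5)
    warning("margin curve does not wind once around the abutment axis")
  circ <- function(r, z) cbind(g$centre_xy[1] + r * cos(th),
                               g$centre_xy[2] + r * sin(th), z)
  r_a1 <- p$d_a1 / 2; r_a2 <- p$d_a2 / 2; r_a3 <- p$d_a3 / 2
  r_b1 <- p$d_ba1 / 2; r_b2 <- p$d_ba2 / 2
  if (r_b2 >= r_a3) stop("borehole wider than the abutment bottom section")
  # access-bore top: just below the dome over the bore footprint
  vsel <- rowSums(sweep(cem$interior$vertices[, 1:2, drop = FALSE], 2,
                        g$centre_xy)^2) < (r_b1 + 0.4)^2
  if (!any(vsel)) stop("dome does not cover the access bore")
  z_bore_top <- min(cem$interior$vertices[vsel, 3]) - 0.1
  z_seat_hi <- z_bore_top - p$l_ba1
  z_seat_lo <- z_bore_top - p$l_ba2
  if (z_seat_lo <= g$z_bottom)
    stop("screw seat below the abutment bottom")
  # ring chain: margin -> taper -> post -> bottom -> up the bore -> cap
  rings <- list(pts,
                circ(r_a1, g$z_neck),
                circ(r_a2, g$z_a2),
                circ(r_a3, g$z_bottom),
                circ(r_b2, g$z_bottom),
                circ(r_b2, z_seat_lo),
                circ(r_b1, z_seat_hi),
                circ(r_b1, z_bore_top))
  lateral <- loft_stack_exact(rings, closed = TRUE, name = "abutment_loft")
  K <- nrow(pts)
  capV <- rbind(rings[[8]], c(g$centre_xy, z_bore_top))
  ci <- nrow(capV)
  a <- seq_len(K); an <- c(a[-1], a[1])
  cap <- trimesh(capV, cbind(ci, a, an), name = "bore_cap")
  solid <- orient_mesh(weld_vertices(
    merge_meshes(list(cem$interior, lateral, cap),
                 name = paste0("abutment_", side)), tol = 1e-9))
  if (!is_watertight(solid)) stop("abutment failed to close")
  attr(solid, "geom") <- c(g[c("z_min", "z_neck", "z_bottom", "z_apex")],
                           list(centre_xy = g$centre_xy,
                                z_bore_top = z_bore_top,
                                z_seat_hi = z_seat_hi, z_seat_lo = z_seat_lo))
  solid
}

# V-groove radial cut of the metric thread profile: depth 5H/8 with
# H = sqrt(3)/2 * pitch; 60 degree flanks; linear run-in/out over half a
# turn at both helix ends.
thread_cut <- function(theta, zeta, p) {
  h <- 5 * sqrt(3) / 16 * p$p_t
  w <- h * tan(pi / 6)
  # groove-root helix: zeta = l_t + p_t * (theta/2pi + n)
  rel <- (zeta - p$l_t) / p$p_t - theta / (2 * pi)
  n <- round(rel)
  s <- n + theta / (2 * pi)               # turn coordinate in [0, n_turns]
  dz <- abs(rel - n) * p$p_t              # axial distance to the root line
  ramp <- pmin(1, pmax(0, pmin(s / 0.5, (p$n_turns - s) / 0.5)))
  cut <- pmax(0, h * (1 - dz / w)) * ramp
  cut[s < -0.5 | s > p$n_turns + 0.5] <- 0
  cut
}

implant_profile_z <- function(p) {
  # depth knots below the neck plane where the outer profile changes;
  # excludes 0 (the rim ring) and l_i1 (the bottom ring), both added by
  # the caller
  fine <- 0.025
  zt0 <- max(p$l_t - 0.6, 0.05)
  zt1 <- min(p$l_t + p$n_turns * p$p_t + 0.6, p$l_i1 - p$r_f - 0.05)
  z <- c(seq(0.05, zt0, length.out = 8),
         seq(zt0 + fine, zt1, by = fine),
         seq(zt1 + 0.05, p$l_i1 - p$r_f, length.out = 8),
         p$l_i1 - p$r_f + p$r_f * sin(seq(0.15, 0.9, length.out = 5) *
                                        pi / 2))
  sort(unique(round(z, 6)))
}

#' Build the implant body
#'
#' Straight cylinder (d_i1 = d_i2) of length `l_i1` below the neck plane,
#' chamfered bore opening (the chamfer cone mates the abutment taper),
#' stepped internal bore, filleted apex and a helical metric V-thread cut
#' into the wall, starting `l_t` below the neck with pitch `p_t` over
#' `n_turns` turns.
#'
#' @param p [implant_params].
#' @param centre_xy implant axis position (mm).
#' @param z_neck height of the neck plane (mm).
#' @param n_theta angular resolution.
#' @param side label for part naming.
#' @return watertight [trimesh] with attribute `geom` (axis, neck, bore
#'   bottom).
#' @export
make_implant_body <- function(p, centre_xy = c(0, 0), z_neck = 0,
                              n_theta = 144, side = "distal") {
  r_o <- p$d_i1 / 2
  r_b1 <- p$d_bi1 / 2; r_b2 <- p$d_bi2 / 2; r_b3 <- p$d_bi3 / 2
  if (p$r_f + 0.2 > p$l_i1) stop("chamfer and fillet exceed the implant length")
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  # inner bore rings from the cap at l_bi4 up to the opening chamfer
  inner <- rbind(c(r_b3, p$l_bi4),
                 c(r_b3, p$l_bi3),
                 c(r_b2, p$l_bi2),
                 c(r_b2, p$l_bi1),
                 c(r_b1, 0))
  zeta <- implant_profile_z(p)
  outer_rings <- lapply(zeta, function(zz) {
    r <- r_o - thread_cut(th, zz, p)
    if (zz > p$l_i1 - p$r_f) {
      rf <- p$l_i1 - p$r_f
      r <- pmin(r, (r_o - p$r_f) + sqrt(pmax(0, p$r_f^2 - (zz - rf)^2)))
    }
    cbind(centre_xy[1] + r * cos(th), centre_xy[2] + r * sin(th),
          z_neck - zz)
  })
  inner_rings <- lapply(seq_len(nrow(inner)), function(i)
    cbind(centre_xy[1] + inner[i, 1] * cos(th),
          centre_xy[2] + inner[i, 1] * sin(th), z_neck - inner[i, 2]))
  # chain: bore cap (fan) -> bore walls up -> opening rim -> top annulus ->
  # outer wall down (threaded) -> fillet -> bottom cap (fan)
  rim_outer <- cbind(centre_xy[1] + r_o * cos(th),
                     centre_xy[2] + r_o * sin(th), z_neck)
  rings <- c(inner_rings, list(rim_outer), outer_rings,
             list(cbind(centre_xy[1] + (r_o - p$r_f) * cos(th),
                        centre_xy[2] + (r_o - p$r_f) * sin(th),
                        z_neck - p$l_i1)))
  solid <- solid_from_sections(rings, name = paste0("implant_", side),
                               cap_first = TRUE, cap_last = TRUE)
  if (!is_watertight(solid)) stop("implant body failed to close")
  attr(solid, "geom") <- list(centre_xy = centre_xy, z_neck = z_neck,
                              z_bore_bottom = z_neck - p$l_bi4,
                              z_apex = z_neck - p$l_i1)
  solid
}

#' Swept helical thread cutter
#'
#' The V-profile of the metric thread (60 degrees, depth 5H/8 for the
#' given pitch) swept along the thread helix about the implant axis; the
#' same surface that [make_implant_body] cuts analytically.  Exposed for
#' inspection/export.
#'
#' @param p [implant_params].
#' @param centre_xy axis position; @param z_neck neck-plane height.
#' @param n_per_turn sweep stations per turn.
#' @return watertight [trimesh] of the cutter solid.
#' @export
make_thread <- function(p, centre_xy = c(0, 0), z_neck = 0,
                        n_per_turn = 64) {
  h <- 5 * sqrt(3) / 16 * p$p_t
  w <- h * tan(pi / 6)
  r_o <- p$d_i1 / 2
  n <- p$n_turns * n_per_turn + 1
  s <- seq(0, p$n_turns, length.out = n)          # turn coordinate
  th <- 2 * pi * s
  zz <- z_neck - (p$l_t + s * p$p_t)
  ramp <- pmin(1, pmax(0, pmin(s / 0.5, (p$n_turns - s) / 0.5)))
  secs <- lapply(seq_len(n), function(i) {
    d <- h * ramp[i]
    # triangular section in the (radial, axial) plane at angle th[i]
    loc <- rbind(c(r_o + 0.05, w), c(r_o - d, 0), c(r_o + 0.05, -w))
    u <- c(cos(th[i]), sin(th[i]), 0)
    cbind(centre_xy[1] + loc[, 1] * u[1], centre_xy[2] + loc[, 1] * u[2],
          zz[i] + loc[, 2])
  })
  solid_from_sections(secs, name = "thread_cutter", cap_first = TRUE,
                      cap_last = TRUE)
}

#' Build the abutment screw
#'
#' Cylindrical head seated in the upper abutment bore, conical underside
#' matching the screw seat, and a shaft of length `l_s` below the seat
#' (diameter below `d_bi3`); errors if the shaft would overrun the implant
#' bore.
#'
#' @param p [implant_params].
#' @param abutment result of [make_abutment] (for the seat datums).
#' @param implant result of [make_implant_body] (for the bore bottom).
#' @param clearance radial clearance between screw and bore walls (mm).
#' @param side label for part naming.
#' @return watertight [trimesh].
#' @export
make_screw <- function(p, abutment, implant, clearance = 0.025,
                       side = "distal") {
  ga <- attr(abutment, "geom"); gi <- attr(implant, "geom")
  z_tip <- ga$z_seat_lo - p$l_s
  if (z_tip < gi$z_bore_bottom)
    stop("screw length l_s exceeds the available bore depth")
  r_head <- p$d_ba1 / 2 - clearance
  r_neck <- p$d_ba2 / 2 - clearance
  r_shaft <- min(p$d_bi3, p$d_ba2) / 2 - clearance
  rz <- rbind(c(r_head, ga$z_bore_top - 0.05),
              c(r_head, ga$z_seat_hi),
              c(r_neck, ga$z_seat_lo),
              c(r_shaft, ga$z_seat_lo - 0.05),
              c(r_shaft, z_tip))
  s <- revolve_profile(rz, n_theta = 96, centre_xy = ga$centre_xy,
                       name = paste0("screw_", side))
  attr(s, "geom") <- list(z_seat = ga$z_seat_lo, z_tip = z_tip)
  s
}

#' Generate the complete implant-type support for an aligned FPD
#'
#' Cement layers, abutments, implant bodies (threaded) and abutment screws
#' on both sides.
#'
#' @param aligned result of [align_fpd].
#' @param params [implant_params].
#' @return named list of watertight parts.
#' @export
generate_implant_support <- function(aligned, params = implant_params()) {
  fpd <- aligned$fpd
  out <- list()
  for (side in c("distal", "mesial")) {
    lumen <- fpd[[side]]
    cem <- make_cement_layer(lumen, params$d_cement, side)
    ab <- make_abutment(cem, params, side)
    g <- attr(ab, "geom")
    im <- make_implant_body(params, centre_xy = g$centre_xy,
                            z_neck = g$z_neck, side = side)
    sc <- make_screw(params, ab, im, side = side)
    out[[paste0("cement_", side)]] <- cem$cement
    out[[paste0("abutment_", side)]] <- ab
    out[[paste0("implant_", side)]] <- im
    out[[paste0("screw_", side)]] <- sc
  }
  out
}
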
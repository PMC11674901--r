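#' Cubic Bezier value profile
#'
#' Four 2D control points `(t, value)` defining a cubic Bernstein
#' polynomial; used to grade the root cross-section scale (and, for the
#' molar, the root translation) along the root axis.
#'
#' @param p0,p1,p2,p3 numeric length-2 control points `(t, value)`.
#' @return object of class `bezier_profile`.
#' @export
bezier_profile <- function(p0, p1, p2, p3) {
  P <- rbind(p0, p1, p2, p3)
  if (is.unsorted(P[, 1])) stop("control-point t coordinates must be nondecreasing")
  structure(list(P = unname(P)), class = "bezier_profile")
}

#' Evaluate a cubic Bezier profile
#'
#' Standard cubic Bernstein combination
#' \eqn{B(t) = (1-t)^3 P_0 + 3(1-t)^2 t P_1 + 3(1-t) t^2 P_2 + t^3 P_3}.
#'
#' @param profile a [bezier_profile].
#' @param t parameter(s) in `[0, 1]`.
#' @return matrix of evaluated 2D points (one row per `t`), columns
#'   `(t_coord, value)`.
#' @export
eval_bezier <- function(profile, t) {
  if (any(t < 0 | t > 1)) stop("bezier parameter t must lie in [0, 1]")
  P <- profile$P
  b <- cbind((1 - t)^3, 3 * (1 - t)^2 * t, 3 * (1 - t) * t^2, t^3)
  out <- b %*% P
  colnames(out) <- c("t_coord", "value")
  out
}

bezier_value <- function(profile, t) eval_bezier(profile, t)[, "value"]

#' Default tooth-support parameters
#'
#' The default values reproduce the study configuration: 0.1 mm cement
#' layer, 0.15 mm loft clearance, 16.3 mm premolar root, 12.8 mm molar
#' roots, 0.3 mm periodontal ligament, 20 grading levels; the Bezier
#' control points taper the root cross-section from full size at the cervix
#' to 5 % at the apex.  `d_r` (mesiodistal furcation-to-apex offset of each
#' molar root) has no published value and defaults to 4 mm.
#'
#' @param d_cement cement layer thickness (mm).
#' @param epsilon clearance between the margin curve and the first root
#'   section (mm).
#' @param d_tooth_premolar,d_tooth_molar root lengths (mm).
#' @param bezier_x,bezier_y cross-section scale profiles ([bezier_profile]).
#' @param bezier_t molar root-translation profile ([bezier_profile]).
#' @param d_r molar root x-offset amplitude (mm).
#' @param d_pdl periodontal-ligament thickness (mm).
#' @param n_levels number of root grading levels.
#' @return list of class `tooth_params`.
#' @export
tooth_params <- function(d_cement = 0.1,
                         epsilon = 0.15,
                         d_tooth_premolar = 16.3,
                         d_tooth_molar = 12.8,
                         bezier_x = bezier_profile(c(0, 1), c(0.08, 0.78),
                                                   c(0.75, 0.55), c(1, 0.05)),
                         bezier_y = bezier_profile(c(0, 1), c(0.2, 0.58),
                                                   c(0.95, 0.5), c(1, 0.05)),
                         bezier_t = bezier_profile(c(0, 0), c(0.35, 0.55),
                                                   c(0.4, 0.9), c(1, 1)),
                         d_r = 4.0,
                         d_pdl = 0.3,
                         n_levels = 20) {
  stopifnot(d_cement > 0, epsilon > 0, d_tooth_premolar > 0,
            d_tooth_molar > 0, d_r >= 0, d_pdl > 0, n_levels >= 2)
  structure(list(d_cement = d_cement, epsilon = epsilon,
                 d_tooth_premolar = d_tooth_premolar,
                 d_tooth_molar = d_tooth_molar,
                 bezier_x = bezier_x, bezier_y = bezier_y,
                 bezier_t = bezier_t, d_r = d_r, d_pdl = d_pdl,
                 n_levels = as.integer(n_levels)),
            class = "tooth_params")
}

#' Default implant-support parameters
#'
#' All lengths/diameters in mm; defaults are the study values.  Axial
#' datums: `l_a1`, `l_a2` are cumulative depths below the margin-curve
#' minimum (the `l_a1` plane is the implant neck plane); `l_a3` is the
#' total abutment length from the dome cap; `l_ba1`, `l_ba2` are depths of
#' the screw-seat cone below the top of the abutment access bore;
#' `l_bi1..l_bi4` are cumulative bore depths below the neck plane.
#'
#' @param d_cement cement thickness.
#' @param l_a1,l_a2,l_a3 abutment section depths/length.
#' @param d_a1,d_a2,d_a3 abutment section diameters.
#' @param l_ba1,l_ba2,d_ba1,d_ba2 abutment borehole dimensions.
#' @param d_i1,d_i2,l_i1 implant body diameters (straight: equal) and length.
#' @param r_c bore-opening chamfer radius; @param r_f apex fillet radius.
#' @param l_bi1,l_bi2,l_bi3,l_bi4,d_bi1,d_bi2,d_bi3 internal bore steps.
#' @param r_b internal edge-break radius (validated, see vignette).
#' @param l_t thread start depth below the neck plane.
#' @param p_t thread pitch; @param n_turns thread turns.
#' @param l_s screw shaft length below the head seat.
#' @return list of class `implant_params`.
#' @export
implant_params <- function(d_cement = 0.1,
                           l_a1 = 1.0, l_a2 = 1.5, l_a3 = 7.0,
                           d_a1 = 3.0, d_a2 = 2.6, d_a3 = 2.6,
                           l_ba1 = 2.0, l_ba2 = 2.2,
                           d_ba1 = 1.6, d_ba2 = 1.3,
                           d_i1 = 5.0, d_i2 = 5.0, l_i1 = 8.0,
                           r_c = 1.5, r_f = 0.2,
                           l_bi1 = 0.5, l_bi2 = 4.0, l_bi3 = 5.0,
                           l_bi4 = 5.3,
                           d_bi1 = 3.0, d_bi2 = 2.6, d_bi3 = 1.1,
                           r_b = 0.2,
                           l_t = 1.5, p_t = 0.5, n_turns = 10,
                           l_s = 4.5) {
  p <- list(d_cement = d_cement, l_a1 = l_a1, l_a2 = l_a2, l_a3 = l_a3,
            d_a1 = d_a1, d_a2 = d_a2, d_a3 = d_a3,
            l_ba1 = l_ba1, l_ba2 = l_ba2, d_ba1 = d_ba1, d_ba2 = d_ba2,
            d_i1 = d_i1, d_i2 = d_i2, l_i1 = l_i1, r_c = r_c, r_f = r_f,
            l_bi1 = l_bi1, l_bi2 = l_bi2, l_bi3 = l_bi3, l_bi4 = l_bi4,
            d_bi1 = d_bi1, d_bi2 = d_bi2, d_bi3 = d_bi3, r_b = r_b,
            l_t = l_t, p_t = p_t, n_turns = as.integer(n_turns), l_s = l_s)
  num <- unlist(p[setdiff(names(p), "n_turns")])
  if (any(num <= 0)) stop("all implant lengths and diameters must be > 0")
  if (abs(d_bi1 - d_a1) > 1e-9)
    stop("d_bi1 must equal d_a1 (bore opening mates the abutment taper)")
  if (abs(d_bi2 - d_a3) > 1e-9)
    stop("d_bi2 must equal d_a3 (bore wall mates the abutment post)")
  if (abs(d_i1 - d_i2) > 1e-9)
    stop("straight implant requires d_i1 = d_i2")
  if (l_t + n_turns * p_t > l_i1)
    stop("thread span l_t + n_turns * p_t exceeds the implant length")
  if (!(l_bi1 < l_bi2 && l_bi2 < l_bi3 && l_bi3 < l_bi4 && l_bi4 < l_i1))
    stop("bore depths l_bi1 < l_bi2 < l_bi3 < l_bi4 < l_i1 required")
  structure(p, class = "implant_params")
}
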
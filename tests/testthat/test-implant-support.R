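# Implant support: abutment sections, implant body dimensions, thread
# helix, screw containment.

implant_axis_sections <- function(mesh, geom, z) {
  section_with_plane(mesh, frame3d(c(geom$centre_xy[1], geom$centre_xy[2], z)))
}

max_diameter <- function(curve, centre_xy) {
  2 * max(sqrt((curve$points[, 1] - centre_xy[1])^2 +
                 (curve$points[, 2] - centre_xy[2])^2))
}

test_that("abutment realises the configured section diameters and bore", {
  parts <- implant_parts()
  ab <- parts$abutment_distal
  g <- attr(ab, "geom")
  expect_watertight(ab)
  # neck plane: maximum section diameter d_a1 = 3.0
  sec <- implant_axis_sections(ab, g, g$z_neck + 1e-3)
  expect_equal(max(vapply(sec, max_diameter, 1, centre_xy = g$centre_xy)),
               3.0, tolerance = 0.01)
  # bottom section diameter d_a3 = 2.6 (annulus: outer curve)
  sec2 <- implant_axis_sections(ab, g, g$z_bottom + 0.05)
  expect_equal(max(vapply(sec2, max_diameter, 1, centre_xy = g$centre_xy)),
               2.6, tolerance = 0.01)
  # the bore removed roughly the bore-cylinder volumes
  p <- implant_params()
  no_bore_vol <- mesh_volume(ab) +
    pi * (p$d_ba2 / 2)^2 * (g$z_seat_lo - g$z_bottom) +
    pi * (p$d_ba1 / 2)^2 * (g$z_bore_top - g$z_seat_hi)
  sec3 <- implant_axis_sections(ab, g, (g$z_neck + g$z_bottom) / 2)
  expect_length(sec3, 2)   # annulus: outer wall + bore wall
})

test_that("implant body has the published neck diameter, length and annular core", {
  parts <- implant_parts()
  im <- parts$implant_distal
  g <- attr(im, "geom")
  expect_watertight(im)
  sec <- implant_axis_sections(im, g, g$z_neck - 0.01)
  expect_equal(max(vapply(sec, max_diameter, 1, centre_xy = g$centre_xy)),
               5.0, tolerance = 0.01)
  expect_equal(g$z_neck - min(im$vertices[, 3]), 8.0, tolerance = 1e-6)
  # mid-height: annulus (outer wall within the thread band, bore inside)
  sec2 <- implant_axis_sections(im, g, g$z_neck - 2.26)
  expect_length(sec2, 2)
  ds <- sort(vapply(sec2, max_diameter, 1, centre_xy = g$centre_xy))
  expect_lt(ds[1], 2.7)           # bore
  expect_gt(ds[2], 4.4)           # thread region outer
  expect_lte(ds[2], 5.0 + 1e-6)
})

test_that("thread root vertices fit a helix with the configured pitch and span", {
  parts <- implant_parts()
  p <- implant_params()
  im <- parts$implant_distal
  g <- attr(im, "geom")
  V <- im$vertices
  r <- sqrt((V[, 1] - g$centre_xy[1])^2 + (V[, 2] - g$centre_xy[2])^2)
  zeta <- g$z_neck - V[, 3]
  h <- 5 * sqrt(3) / 16 * p$p_t
  sel <- r < p$d_i1 / 2 - h + 0.02 & r > 2 & zeta > p$l_t + 0.8 &
    zeta < p$l_t + p$n_turns * p$p_t - 0.8
  expect_gt(sum(sel), 200)
  th <- atan2(V[sel, 2] - g$centre_xy[2], V[sel, 1] - g$centre_xy[1])
  zz <- zeta[sel]
  o <- order(zz); th <- th[o]; zz <- zz[o]
  for (i in seq_along(th)[-1]) {
    while (th[i] < th[i - 1] - pi) th[i] <- th[i] + 2 * pi
    while (th[i] > th[i - 1] + pi) th[i] <- th[i] - 2 * pi
  }
  pitch_fit <- unname(stats::coef(stats::lm(zz ~ th))[2]) * 2 * pi
  expect_equal(pitch_fit, 0.5, tolerance = 0.02 * 0.5)
  # helix spans n_turns revolutions
  expect_equal(diff(range(th)) / (2 * pi) * pitch_fit,
               diff(range(zz)), tolerance = 0.05)
  # thread radius bounds
  in_thread <- zeta > p$l_t & zeta < p$l_t + p$n_turns * p$p_t & r > 2
  expect_lte(max(r[in_thread]), p$d_i1 / 2 + 1e-9)
  expect_gte(min(r[in_thread]), p$d_i1 / 2 - h - 1e-9)
})

test_that("threaded volume deficit matches the Pappus estimate", {
  p <- implant_params()
  im <- make_implant_body(p)
  # independent oracle: unthreaded volume by numeric revolution of the
  # known axial profile, pi * integral (r_out^2 - r_in^2) d zeta
  zf <- seq(0, p$l_i1, by = 1e-4)
  r_out <- ifelse(zf <= p$l_i1 - p$r_f, p$d_i1 / 2,
                  (p$d_i1 / 2 - p$r_f) +
                    sqrt(pmax(0, p$r_f^2 - (zf - (p$l_i1 - p$r_f))^2)))
  r_in <- rep(0, length(zf))
  seg <- zf <= p$l_bi1
  r_in[seg] <- p$d_bi1 / 2 + (p$d_bi2 / 2 - p$d_bi1 / 2) * zf[seg] / p$l_bi1
  seg <- zf > p$l_bi1 & zf <= p$l_bi2
  r_in[seg] <- p$d_bi2 / 2
  seg <- zf > p$l_bi2 & zf <= p$l_bi3
  r_in[seg] <- p$d_bi2 / 2 + (p$d_bi3 / 2 - p$d_bi2 / 2) *
    (zf[seg] - p$l_bi2) / (p$l_bi3 - p$l_bi2)
  seg <- zf > p$l_bi3 & zf <= p$l_bi4
  r_in[seg] <- p$d_bi3 / 2
  v_unthreaded <- pi * sum(r_out^2 - r_in^2) * 1e-4
  h <- 5 * sqrt(3) / 16 * p$p_t
  w <- h * tan(pi / 6)
  pappus <- p$n_turns * (h * w) * 2 * pi * (p$d_i1 / 2 - h / 3)
  deficit <- v_unthreaded - mesh_volume(im)
  expect_gt(deficit, 0)
  expect_lt(abs(deficit - pappus) / pappus, 0.15)
})

test_that("doubling the turns doubles the threaded axial span", {
  g10 <- make_implant_body(implant_params(n_turns = 10, p_t = 0.3))
  g5 <- make_implant_body(implant_params(n_turns = 5, p_t = 0.3))
  span_of <- function(im, p_t, n_turns) {
    g <- attr(im, "geom")
    V <- im$vertices
    r <- sqrt(V[, 1]^2 + V[, 2]^2)
    zeta <- g$z_neck - V[, 3]
    h <- 5 * sqrt(3) / 16 * p_t
    # outer-wall vertices cut below the crest level, away from the apex
    # fillet and the bore
    diff(range(zeta[r < 2.5 - 0.6 * h & r > 2 & zeta < 7.5]))
  }
  s10 <- span_of(g10, 0.3, 10); s5 <- span_of(g5, 0.3, 5)
  expect_equal(s10 / s5, 2, tolerance = 0.15)
})

test_that("thread parameters outside the body are rejected", {
  expect_error(implant_params(n_turns = 20, p_t = 0.5), "exceeds")
  expect_error(implant_params(d_i2 = 4.0), "straight")
  expect_error(implant_params(d_bi1 = 2.8), "d_a1")
})

test_that("screw seats in the abutment and stays inside the bores", {
  parts <- implant_parts()
  p <- implant_params()
  sc <- parts$screw_distal
  ab <- parts$abutment_distal
  im <- parts$implant_distal
  expect_watertight(sc)
  expect_gt(mesh_volume(sc), 0)
  gs <- attr(sc, "geom")
  expect_equal(gs$z_seat - gs$z_tip, 4.5, tolerance = 1e-9)
  # containment: no screw sample point inside abutment or implant material
  set.seed(41)
  bb <- fpdgen:::bbox_internal(sc)
  P <- cbind(stats::runif(6000, bb[1, 1], bb[2, 1]),
             stats::runif(6000, bb[1, 2], bb[2, 2]),
             stats::runif(6000, bb[1, 3], bb[2, 3]))
  Pin <- P[fpdgen:::cpp_points_in_mesh(P, sc$vertices, sc$faces), ,
           drop = FALSE]
  expect_gt(nrow(Pin), 200)
  expect_lt(mean(fpdgen:::cpp_points_in_mesh(Pin, ab$vertices, ab$faces)),
            0.001)
  expect_lt(mean(fpdgen:::cpp_points_in_mesh(Pin, im$vertices, im$faces)),
            0.001)
  # an overlong screw is rejected
  expect_error(make_screw(implant_params(l_s = 12), ab, im), "bore depth")
})

test_that("implant body sections are circular before threading (CI ~ 1)", {
  p <- implant_params(n_turns = 2, l_t = 5.0)   # leave the upper wall smooth
  im <- make_implant_body(p)
  g <- attr(im, "geom")
  for (z in c(g$z_neck - 0.8, g$z_neck - 2.0)) {
    sec <- implant_axis_sections(im, g, z)
    outer <- sec[[which.max(vapply(sec, function(cv)
      max_diameter(cv, g$centre_xy), 1))]]
    ci <- circularity_index(list(outer), normal = c(0, 0, 1))$ci
    expect_gt(ci, 0.999)
  }
})
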
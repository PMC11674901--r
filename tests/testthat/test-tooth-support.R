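# Tooth support: Bezier profiles, cement shell, rooted abutment teeth,
# periodontal ligament.

test_that("cubic Bezier profiles hit their endpoints and closed-form midpoint", {
  bx <- tooth_params()$bezier_x
  expect_equal(as.numeric(eval_bezier(bx, 0)), c(0, 1))
  expect_equal(as.numeric(eval_bezier(bx, 1)), c(1, 0.05))
  # midpoint of a cubic: (P0 + 3 P1 + 3 P2 + P3) / 8
  expect_equal(as.numeric(eval_bezier(bx, 0.5)), c(0.43625, 0.63),
               tolerance = 1e-12)
  expect_error(eval_bezier(bx, 1.2), "\\[0, 1\\]")
  expect_error(bezier_profile(c(0, 1), c(0.5, 1), c(0.3, 1), c(1, 1)),
               "nondecreasing")
})

test_that("cement layer realises its thickness and exposes the interior surface", {
  al <- tooth_aligned()
  cem <- make_cement_layer(al$fpd$mesial, 0.1, "mesial")
  expect_watertight(cem$cement)
  d <- distance_to_mesh(cem$interior$vertices, al$fpd$mesial)
  expect_equal(mean(d), 0.1, tolerance = 0.05 * 0.1)
  # thin-shell volume approximation
  expect_equal(mesh_volume(cem$cement), mesh_area(al$fpd$mesial) * 0.1,
               tolerance = 0.2 * mesh_area(al$fpd$mesial) * 0.1)
  expect_true(cem$c_interior$closed)
  expect_error(make_cement_layer(al$fpd$mesial, 0), "d_cement")
})

test_that("premolar root reaches epsilon + d_tooth below the margin with shrinking sections", {
  al <- tooth_aligned()
  pm <- tooth_parts()$tooth_44
  cem <- make_cement_layer(al$fpd$mesial, 0.1, "mesial")
  z_min <- min(cem$c_interior$points[, 3])
  expect_watertight(pm)
  expect_equal(attr(pm, "z_apex"), z_min - 0.15 - 16.3, tolerance = 1e-6)
  expect_equal(min(pm$vertices[, 3]), z_min - 0.15 - 16.3, tolerance = 1e-6)
  # slice-and-measure: cross-section area decreases toward the apex
  zs <- seq(z_min - 1, z_min - 15.5, length.out = 8)
  areas <- vapply(zs, function(z) {
    sec <- section_with_plane(pm, frame3d(c(0, 0, z)))
    sum(vapply(sec, function(cv)
      fpdgen:::polygon_area_perimeter(cv, c(0, 0, 1))$area, 1))
  }, 1)
  expect_true(all(diff(areas) < 0))
})

test_that("molar roots merge into one watertight solid that forks below the furcation", {
  al <- tooth_aligned()
  mo <- tooth_parts()$tooth_47
  expect_watertight(mo)
  z_start <- attr(mo, "z_start")
  z_apex <- attr(mo, "z_apex")
  expect_equal(z_apex, z_start - 12.8, tolerance = 1e-6)
  d_root <- z_start - z_apex
  n_comp <- function(frac) {
    sec <- section_with_plane(mo, frame3d(c(0, 0, z_start - frac * d_root)))
    length(Filter(function(cv) cv$closed, sec))
  }
  expect_equal(n_comp(0.10), 1)
  expect_equal(n_comp(0.90), 2)
})

test_that("molar is mirror-symmetric for an x-symmetric margin curve", {
  # symmetric synthetic margin: the +x and -x roots must mirror
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  r <- 4 * (1 + 0.2 * cos(2 * th))
  cup <- fpdgen:::lumen_cup(c(0, 0), 4, 4.5,
                            function(t) 1 + 0.2 * cos(2 * t),
                            function(t) rep(0, length(t)), name = "sym")
  cem <- make_cement_layer(cup, 0.1, "sym")
  mo <- make_two_root(cem, tooth_params(), c(0, 0, 0), name = "sym47")
  V <- mo$vertices[mo$vertices[, 3] < -2, ]
  xr <- range(V[, 1])
  expect_equal(abs(xr[1]), abs(xr[2]), tolerance = 0.05)
})

test_that("PDL shell realises its thickness and encloses the root apex", {
  pdl <- tooth_parts()$pdl_44
  pm <- tooth_parts()$tooth_44
  expect_watertight(pdl)
  rs <- attr(pm, "root_surface")
  outer <- suppressWarnings(offset_along_normals(rs, 0.3, "outward"))
  d <- distance_to_mesh(outer$vertices, rs)
  expect_equal(mean(d), 0.3, tolerance = 0.05 * 0.3)
  # the apex of the root lies strictly inside the PDL outer envelope
  apex <- pm$vertices[which.min(pm$vertices[, 3]), , drop = FALSE]
  expect_lt(min(pdl$vertices[, 3]), apex[3])
  expect_error(make_pdl(rs, -0.1), "d_pdl")
})

test_that("PDL on a spherical-cap root reproduces the analytic shell volume", {
  s <- sphere_mesh(radius = 5, n_theta = 96, n_phi = 48)
  keep <- apply(s$faces, 1, function(f) all(s$vertices[f, 3] < 1e-9))
  cap <- trimesh(s$vertices, s$faces[keep, , drop = FALSE], name = "cap")
  pdl <- make_pdl(cap, 0.3)
  expect_watertight(pdl)
  v_analytic <- 2 / 3 * pi * (5.3^3 - 5^3)
  expect_equal(mesh_volume(pdl), v_analytic, tolerance = 0.05 * v_analytic)
})

test_that("cement, tooth and PDL do not interpenetrate beyond measurement resolution", {
  al <- tooth_aligned()
  parts <- tooth_parts()
  cem <- parts$cement_mesial
  pm <- parts$tooth_44
  pdl <- parts$pdl_44
  # sample points inside each part; none may fall inside a mate
  sample_inside <- function(m, n = 4000) {
    bb <- fpdgen:::bbox_internal(m)
    P <- cbind(stats::runif(n, bb[1, 1], bb[2, 1]),
               stats::runif(n, bb[1, 2], bb[2, 2]),
               stats::runif(n, bb[1, 3], bb[2, 3]))
    P[fpdgen:::cpp_points_in_mesh(P, m$vertices, m$faces), , drop = FALSE]
  }
  set.seed(31)
  pin <- sample_inside(pm)
  frac_in_cem <- mean(fpdgen:::cpp_points_in_mesh(pin, cem$vertices,
                                                  cem$faces))
  frac_in_pdl <- mean(fpdgen:::cpp_points_in_mesh(pin, pdl$vertices,
                                                  pdl$faces))
  expect_lt(frac_in_cem, 0.001)
  expect_lt(frac_in_pdl, 0.001)
})

test_that("root volume responds continuously to a small d_tooth perturbation", {
  al <- tooth_aligned()
  cem <- make_cement_layer(al$fpd$mesial, 0.1, "mesial")
  p0 <- tooth_params()
  p1 <- tooth_params(d_tooth_premolar = 16.3 * 1.01)
  v0 <- mesh_volume(make_single_root(cem, p0, al$landmarks$p_mesial))
  v1 <- mesh_volume(make_single_root(cem, p1, al$landmarks$p_mesial))
  expect_gt(v1, v0)
  expect_lt((v1 - v0) / v0, 0.03)
})
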
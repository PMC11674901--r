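# Mesh kernel primitives: boundary loops, bounding boxes, sections,
# offsets, lofts, Booleans, rigid transforms.

test_that("naked edge loops: closed meshes have none, open tubes chain correctly", {
  expect_length(naked_edge_loops(box_mesh(c(0, 0, 0), c(1, 1, 1))), 0)
  tube <- cylinder_mesh(radius = 2, height = 5, caps = FALSE)
  loops <- naked_edge_loops(tube)
  expect_length(loops, 2)
  expect_true(all(vapply(loops, function(l) l$closed, TRUE)))
  # hemisphere without base: one loop with the analytic circumference
  s <- sphere_mesh(radius = 3, n_theta = 96, n_phi = 48)
  keep <- apply(s$faces, 1, function(f) all(s$vertices[f, 3] > -1e-9))
  hemi <- trimesh(s$vertices, s$faces[keep, , drop = FALSE])
  loops <- naked_edge_loops(hemi)
  expect_length(loops, 1)
  expect_equal(polyline_length(loops[[1]]), 2 * pi * 3, tolerance = 1e-3)
})

test_that("minimal oriented bounding box recovers boxes in any pose and spheres", {
  b <- box_mesh(c(0, 0, 0), c(2, 3, 5))
  ob <- min_oriented_bounding_box(b)
  expect_equal(sort(ob$extents), c(2, 3, 5), tolerance = 1e-9)
  expect_equal(box_volume(ob), 30, tolerance = 1e-9)
  # rotation invariance of the volume
  set.seed(11)
  for (k in 1:3) {
    R <- fpdgen:::rot_xyz(stats::runif(3, 0, 2 * pi))
    obr <- min_oriented_bounding_box(apply_rigid(b, R, stats::runif(3)))
    expect_lt(abs(box_volume(obr) - 30) / 30, 0.01)
  }
  # sphere: compare against a brute-force orientation grid
  s <- sphere_mesh(radius = 1, n_theta = 48, n_phi = 24)
  obs <- min_oriented_bounding_box(s)
  grid_best <- Inf
  for (a in seq(0, pi / 2, length.out = 5))
    for (bb in seq(0, pi / 2, length.out = 5)) {
      R <- fpdgen:::rot_xyz(c(a, bb, 0))
      E <- s$vertices %*% t(R)
      grid_best <- min(grid_best, prod(apply(E, 2, max) - apply(E, 2, min)))
    }
  expect_lte(box_volume(obs), grid_best + 1e-9)
  expect_equal(obs$extents, rep(2, 3), tolerance = 0.01)
})

test_that("oriented bounding box flags degenerate coplanar input", {
  flat <- trimesh(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0),
                  rbind(c(1, 2, 3), c(2, 4, 3)))
  ob <- min_oriented_bounding_box(flat)
  expect_true(isTRUE(attr(ob, "degenerate")))
  expect_lt(min(ob$extents), 1e-9)
})

test_that("plane sections produce exact closed curves", {
  s <- sphere_mesh(radius = 1, n_theta = 128, n_phi = 64)
  sec <- section_with_plane(s, frame3d(c(0, 0, 0)))
  expect_length(sec, 1)
  expect_true(sec[[1]]$closed)
  expect_equal(polyline_length(sec[[1]]), 2 * pi, tolerance = 1e-3)
  ap <- fpdgen:::polygon_area_perimeter(sec[[1]], c(0, 0, 1))
  expect_equal(ap$area, pi, tolerance = 1e-2)
  # points satisfy the plane equation
  expect_lt(max(abs(sec[[1]]$points[, 3])), 1e-9)
  # plane outside the mesh
  expect_length(section_with_plane(s, frame3d(c(0, 0, 5))), 0)
  # torus sectioned by a plane containing its axis: two closed curves
  to <- torus_mesh(R = 3, r = 1)
  sec2 <- section_with_plane(to, frame_from_zx(c(0, 0, 0), c(0, 1, 0),
                                               c(1, 0, 0)))
  expect_length(sec2, 2)
  expect_true(all(vapply(sec2, function(l) l$closed, TRUE)))
})

test_that("normal offsets reproduce analytic radius changes and translations", {
  s <- sphere_mesh(radius = 5, n_theta = 96, n_phi = 48)
  for (d in c(0.1, 0.5, 2)) {   # all below r/2
    si <- offset_along_normals(s, d, "inward")
    r <- sqrt(rowSums(si$vertices^2))
    expect_equal(mean(r), 5 - d, tolerance = 1e-4)
    expect_lt(diff(range(r)), 2e-4)
  }
  # flat patch: rigid translation along the normal
  flat <- trimesh(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0),
                  rbind(c(1, 2, 3), c(2, 4, 3)))
  up <- offset_along_normals(flat, 0.7, "outward")
  shift <- up$vertices - flat$vertices
  expect_equal(abs(shift[, 3]), rep(0.7, 4), tolerance = 1e-12)
  expect_equal(shift[, 1:2], matrix(0, 4, 2), tolerance = 1e-12)
  expect_error(offset_along_normals(flat, -1), "distance")
})

test_that("lofts match analytic lateral areas and reject degenerate input", {
  c1 <- circle_polyline(1, c(0, 0, 0))
  c2 <- circle_polyline(1, c(0, 0, 1))
  cyl <- loft(c1, c2)
  expect_equal(mesh_area(cyl), 2 * pi, tolerance = 0.01 * 2 * pi)
  # frustum r=1 -> r=0.5, height 1: A = pi (r1 + r2) slant
  c3 <- circle_polyline(0.5, c(0, 0, 1))
  fr <- loft(c1, c3)
  slant <- sqrt(1 + 0.25)
  expect_equal(mesh_area(fr), pi * 1.5 * slant, tolerance = 0.01 * pi * 1.5)
  # loft to a translated rigid copy: strip of the translation width
  sq <- polyline3d(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                   closed = TRUE)
  sq2 <- apply_rigid(sq, diag(3), c(0, 0, 0.8))
  strip <- loft(sq, sq2, n = 64)
  expect_equal(mesh_area(strip), 4 * 0.8, tolerance = 1e-6)
  expect_error(loft(c1, c1), "degenerate")
})

test_that("Boolean operations are volume-exact on boxes", {
  a <- box_mesh(c(0, 0, 0), c(2, 2, 2))
  b <- box_mesh(c(0.5, 0.5, 0.5), c(1.5, 1.5, 1.5))
  d <- mesh_boolean(a, b, "difference")
  expect_watertight(d)
  expect_equal(mesh_volume(d), 7, tolerance = 1e-9)
  u <- mesh_boolean(box_mesh(c(0, 0, 0), c(1, 1, 1)),
                    box_mesh(c(0.5, 0, 0), c(1.5, 1, 1)), "union")
  expect_equal(mesh_volume(u), 1.5, tolerance = 1e-9)
  # subtracting a disjoint solid changes nothing
  far <- box_mesh(c(5, 5, 5), c(6, 6, 6))
  d2 <- mesh_boolean(a, far, "difference")
  expect_equal(mesh_volume(d2), 8, tolerance = 1e-9)
  expect_error(mesh_boolean(a, cylinder_mesh(caps = FALSE), "union"),
               "watertight")
})

test_that("Boolean volume arithmetic holds on random box pairs", {
  set.seed(7)
  for (k in 1:6) {
    lo1 <- stats::runif(3, -1, 0); hi1 <- lo1 + stats::runif(3, 0.5, 2)
    lo2 <- stats::runif(3, -1, 0); hi2 <- lo2 + stats::runif(3, 0.5, 2)
    a <- box_mesh(lo1, hi1); b <- box_mesh(lo2, hi2)
    if (k > 3)
      b <- apply_rigid(b, fpdgen:::rot_xyz(stats::runif(3, 0, 1)),
                       c(0.1, 0, 0))
    vd <- mesh_volume(mesh_boolean(a, b, "difference"))
    vi <- mesh_volume(mesh_boolean(a, b, "intersection"))
    expect_lt(abs(vd + vi - mesh_volume(a)) / mesh_volume(a), 0.001)
  }
})

test_that("voxel Boolean path is watertight and volume-faithful", {
  a <- box_mesh(c(0, 0, 0), c(2, 2, 2))
  b <- box_mesh(c(0.5, 0.5, 0.5), c(1.5, 1.5, 1.5))
  d <- mesh_boolean(a, b, "difference", method = "voxel", pitch = 0.05)
  expect_watertight(d)
  expect_equal(mesh_volume(d), 7, tolerance = 0.01)
})

test_that("rigid frame transforms preserve distances and compose to identity", {
  m <- sphere_mesh(radius = 2, n_theta = 24, n_phi = 12)
  f1 <- frame3d(c(1, 2, 3))
  expect_equal(transform_to_frame(m, f1, f1)$vertices, m$vertices,
               tolerance = 1e-12)
  moved <- transform_to_frame(m, f1, frame3d())
  expect_equal(moved$vertices, sweep(m$vertices, 2, c(1, 2, 3)),
               tolerance = 1e-12)
  set.seed(5)
  for (k in 1:4) {
    fa <- frame3d(stats::runif(3), fpdgen:::rot_xyz(stats::runif(3, 0, 2 * pi)))
    fb <- frame3d(stats::runif(3), fpdgen:::rot_xyz(stats::runif(3, 0, 2 * pi)))
    mt <- transform_to_frame(m, fa, fb)
    d0 <- as.matrix(stats::dist(m$vertices[1:20, ]))
    d1 <- as.matrix(stats::dist(mt$vertices[1:20, ]))
    expect_lt(max(abs(d0 - d1)), 1e-9)
    back <- transform_to_frame(mt, fb, fa)
    expect_lt(max(abs(back$vertices - m$vertices)), 1e-9)
  }
})

test_that("constructive primitives are watertight with analytic volumes", {
  expect_watertight(box_mesh(c(0, 0, 0), c(1, 2, 3)))
  s <- sphere_mesh(radius = 2, n_theta = 96, n_phi = 48)
  expect_watertight(s)
  expect_equal(mesh_volume(s), 4 / 3 * pi * 8, tolerance = 0.01 * 4 / 3 * pi * 8)
  cy <- cylinder_mesh(radius = 1.5, height = 4, n_theta = 128)
  expect_watertight(cy)
  expect_equal(mesh_volume(cy), pi * 2.25 * 4, tolerance = 0.01 * pi * 9)
})
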
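# Bone segment, insertion frame, Boolean cavity, defect carving, PDL trim.

test_that("bone frame is orthonormal with the configured span on the crest", {
  bone <- bone_d1()
  bf <- build_bone_frame(bone, 30)
  fr <- bf$frame
  expect_equal(fr$axes %*% t(fr$axes), diag(3), tolerance = 1e-9)
  expect_equal(det(fr$axes), 1, tolerance = 1e-9)
  expect_equal(sqrt(sum((bf$p_mesial - bf$p_distal)^2)), 30,
               tolerance = 0.01 * 30)
  # projected points sit on the crestal surface
  expect_equal(bf$p_distal[3], bone$crest_z, tolerance = 1e-9)
  expect_error(build_bone_frame(bone, 100), "span")
})

test_that("placement puts the distal landmark d_bone above the crest, rigidly", {
  al <- implant_aligned()
  parts <- implant_parts()
  bone <- bone_d1()
  bf <- build_bone_frame(bone, sqrt(sum((al$landmarks$p_mesial -
                                           al$landmarks$p_distal)^2)))
  assembly <- c(list(surface = al$fpd$surface, distal = al$fpd$distal,
                     mesial = al$fpd$mesial), parts)
  placed <- place_assembly(assembly, frame3d(), bf, d_bone = 2.8,
                           bone = bone)
  lm <- extract_landmarks(fpd_model(placed$surface, placed$distal,
                                    placed$mesial))
  # ray from the landmark down the bone vertical to the intact crest
  expect_equal(lm$p_distal[3] - bone$crest_z, 2.8, tolerance = 1e-6)
  # rigid: inter-part distances preserved
  d0 <- sqrt(sum((colMeans(parts$implant_distal$vertices) -
                    colMeans(parts$screw_mesial$vertices))^2))
  d1 <- sqrt(sum((colMeans(placed$implant_distal$vertices) -
                    colMeans(placed$screw_mesial$vertices))^2))
  expect_equal(d0, d1, tolerance = 1e-9)
  # implant tips reach below the crest
  expect_lt(min(placed$implant_distal$vertices[, 3]), bone$crest_z)
  expect_error(place_assembly(assembly, frame3d(), bf, d_bone = 50,
                              bone = bone),
               "reach")
})

test_that("subtracting the supports removes the submerged volume from the bone", {
  al <- implant_aligned()
  parts <- implant_parts()
  bone <- bone_d1()
  bf <- build_bone_frame(bone, sqrt(sum((al$landmarks$p_mesial -
                                           al$landmarks$p_distal)^2)))
  placed <- place_assembly(parts, frame3d(), bf, d_bone = 2.8)
  v0 <- mesh_volume(bone$outer)
  sub <- subtract_assembly(bone, placed[c("implant_distal",
                                          "implant_mesial")])
  expect_watertight(sub$outer)
  # submerged volume of the implants (below the crest plane)
  submerged <- 0
  for (nm in c("implant_distal", "implant_mesial")) {
    m <- placed[[nm]]
    zf <- seq(min(m$vertices[, 3]), bone$crest_z, length.out = 400)
    areas <- vapply(zf[-length(zf)], function(z) {
      sec <- section_with_plane(m, frame3d(c(0, 0, z + 1e-4)))
      a <- vapply(sec, function(cv)
        fpdgen:::polygon_area_perimeter(cv, c(0, 0, 1))$area, 1)
      if (length(a) == 0) 0 else max(a) - ifelse(length(a) > 1, min(a), 0)
    }, 1)
    submerged <- submerged + sum(areas) * diff(zf)[1]
  }
  removed <- v0 - mesh_volume(sub$outer)
  expect_equal(removed, submerged, tolerance = 0.01 * submerged)
  # subtracting a non-intersecting part leaves the bone unchanged
  far <- box_mesh(c(200, 200, 200), c(201, 201, 201))
  sub2 <- subtract_assembly(bone, list(far))
  expect_equal(mesh_volume(sub2$outer), v0, tolerance = 1e-9)
})

test_that("saucer defects realise depth, width and idempotence", {
  bone <- bone_d1()
  v0 <- mesh_volume(bone$outer)
  # depth 0 is the identity
  b0 <- carve_defect(bone, defect_spec(0, sites = 24))
  expect_identical(b0$outer$vertices, bone$outer$vertices)
  b3 <- suppressWarnings(carve_defect(bone, defect_spec(3, sites = 24)))
  dev <- bone$outer$vertices[, 3] - b3$outer$vertices[, 3]
  expect_equal(max(dev), 3.0, tolerance = 0.05)
  b2 <- carve_defect(bone, defect_spec(2, sites = 24))
  dev2 <- bone$outer$vertices[, 3] - b2$outer$vertices[, 3]
  sel <- dev2 > 0.01
  expect_equal(diff(range(bone$outer$vertices[sel, 1])), 10,
               tolerance = 0.2)
  # carving twice with the same spec changes nothing
  b2b <- carve_defect(b2, defect_spec(2, sites = 24))
  expect_identical(b2b$outer$vertices, b2$outer$vertices)
  expect_watertight(b2$outer)
  # defect volume grows strictly with depth
  vols <- vapply(c(0, 1, 2, 3), function(d)
    v0 - mesh_volume(suppressWarnings(
      carve_defect(bone, defect_spec(d, sites = 24)))$outer), 1)
  expect_true(all(diff(vols) > 0))
  # deep defects in soft bone warn about entering the cancellous layer
  d4 <- make_bone_fixture("D4")
  expect_warning(carve_defect(d4, defect_spec(3, sites = 24)), "cancellous")
})

test_that("PDL trimming stops at the crest and shrinks monotonically with depth", {
  al <- tooth_aligned()
  parts <- tooth_parts()
  bone <- bone_d1()
  bf <- build_bone_frame(bone, sqrt(sum((al$landmarks$p_mesial -
                                           al$landmarks$p_distal)^2)))
  placed <- place_assembly(parts, frame3d(), bf, d_bone = 2.8)
  pdl <- placed$pdl_44
  tr0 <- trim_pdl(pdl, bone)
  expect_watertight(tr0)
  expect_equal(max(tr0$vertices[, 3]), bone$crest_z, tolerance = 0.05)
  areas <- vapply(c(0, 1, 2, 3), function(d) {
    b <- suppressWarnings(
      carve_defect(bone, defect_spec(d, sites = c(bf$p_distal[1],
                                                  bf$p_mesial[1]))))
    mesh_area(trim_pdl(pdl, b))
  }, 1)
  expect_true(all(diff(areas) < 0))
  # a PDL fully above the bone cannot be trimmed
  up <- apply_rigid(pdl, diag(3), c(0, 0, 40))
  expect_error(trim_pdl(up, bone), "above the bone")
})
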
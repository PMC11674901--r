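# FPD alignment: landmarks, gingival face, frame construction, rigid
# alignment and its invariances.

test_that("landmarks match the generator's recorded margin centres", {
  fx <- make_fpd_fixture("tooth", seed = 2)
  lm <- extract_landmarks(fx$fpd)
  expect_equal(lm$p_distal, fx$truth$p_distal, tolerance = 1e-6)
  expect_equal(lm$p_mesial, fx$truth$p_mesial, tolerance = 1e-6)
  expect_equal(lm$p_md, (lm$p_distal + lm$p_mesial) / 2, tolerance = 1e-12)
  # watertight lumen has no margin curve
  expect_error(extract_landmarks(fpd_model(fx$fpd$surface,
                                           sphere_mesh(radius = 1),
                                           fx$fpd$mesial)),
               "open")
})

test_that("gingival face detection picks the face nearest the mesiodistal midpoint", {
  b <- oriented_box(frame3d(c(0, 0, 0)), c(2, 2, 2))
  gf <- find_gingival_face(b, c(0, 0, -1))       # bottom face centre
  expect_equal(gf$gingival, 5)                   # -z face
  expect_equal(gf$occlusal, 6)
  # equidistant: lowest face index wins
  gf2 <- find_gingival_face(b, c(0, 0, 0))
  expect_equal(gf2$gingival, 1)
  # fixture: matches the generator's known gingival side
  fx <- make_fpd_fixture("implant", seed = 4)
  lm <- extract_landmarks(fx$fpd)
  box <- min_oriented_bounding_box(fx$fpd$merged)
  gf3 <- find_gingival_face(box, lm$p_md)
  n <- gf3$normals[gf3$gingival, ]
  expect_gt(sum(n * fx$truth$gingival_normal), 0.98)
})

test_that("FPD frame is orthonormal with z occlusal and x along the lumen line", {
  fx <- make_fpd_fixture("tooth", seed = 6)
  lm <- extract_landmarks(fx$fpd)
  box <- min_oriented_bounding_box(fx$fpd$merged)
  fr <- build_fpd_frame(lm, box, fx$fpd$merged)
  expect_equal(fr$axes %*% t(fr$axes), diag(3), tolerance = 1e-9)
  expect_equal(det(fr$axes), 1, tolerance = 1e-9)
  expect_equal(fr$origin, lm$p_distal, tolerance = 1e-12)
  # x axis is the in-plane projection of the mesiodistal line
  md <- lm$p_mesial - lm$p_distal
  expect_equal(sum(fr$axes[2, ] * md), 0, tolerance = 1e-9)
  # z points occlusally (away from the recorded gingival normal)
  expect_lt(sum(fr$axes[3, ] * fx$truth$gingival_normal), -0.98)
})

test_that("alignment sends p_distal to the origin and p_mesial to the +x axis", {
  for (type in c("tooth", "implant")) {
    al <- align_fpd(make_fpd_fixture(type, seed = 8)$fpd)
    expect_lt(sqrt(sum(al$landmarks$p_distal^2)), 1e-9)
    expect_gt(al$landmarks$p_mesial[1], 0)
    expect_lt(abs(al$landmarks$p_mesial[2]), 1e-9)
  }
})

test_that("alignment is idempotent and pose-invariant", {
  fx <- make_fpd_fixture("tooth", seed = 3, pose = FALSE)
  al0 <- align_fpd(fx$fpd)
  al1 <- align_fpd(al0$fpd)
  expect_lt(max(abs(al1$fpd$merged$vertices - al0$fpd$merged$vertices)), 1e-9)
  set.seed(99)
  for (k in 1:3) {
    R <- fpdgen:::random_rotation()
    tr <- stats::runif(3, -30, 30)
    posed <- fpd_model(apply_rigid(fx$fpd$surface, R, tr),
                       apply_rigid(fx$fpd$distal, R, tr),
                       apply_rigid(fx$fpd$mesial, R, tr))
    alR <- align_fpd(posed)
    expect_lt(max(abs(alR$fpd$merged$vertices - al0$fpd$merged$vertices)),
              1e-6)
  }
})

test_that("landmarks are invariant to sub-mesh concatenation order", {
  fx <- make_fpd_fixture("implant", seed = 9)
  lm1 <- extract_landmarks(fx$fpd)
  swapped <- fpd_model(fx$fpd$surface, fx$fpd$distal, fx$fpd$mesial)
  swapped$merged <- merge_meshes(list(fx$fpd$mesial, fx$fpd$surface,
                                      fx$fpd$distal))
  lm2 <- extract_landmarks(swapped)
  expect_equal(lm1$p_distal, lm2$p_distal, tolerance = 1e-12)
})
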
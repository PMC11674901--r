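# Support-type detection: sectioning protocol, circularity index,
# threshold rule.

test_that("cylinder sections give unit circularity and the protocol drops end curves", {
  cyl <- cylinder_mesh(radius = 2, height = 10, n_theta = 256, n_z = 16)
  l_p <- rbind(c(0, 0, -1), c(0, 0, 11))
  st <- section_lumen(cyl, l_p, n_planes = 100)
  expect_true(all(vapply(st$curves, function(cv) cv$closed, TRUE)))
  # all retained curves are circles of the cylinder radius
  for (cv in st$curves[c(1, length(st$curves) %/% 2, length(st$curves))]) {
    r <- sqrt(rowSums(cv$points[, 1:2]^2))
    expect_equal(mean(r), 2, tolerance = 1e-3)
  }
  ci <- circularity_index(st)
  expect_equal(round(ci$ci, 2), 1)
  expect_true(all(ci$per_curve$ratio <= 1 + 1e-6))
  # a plane range missing the lumen entirely (line above the solid)
  expect_error(section_lumen(cyl, rbind(c(0, 0, 20), c(0, 0, 30))),
               "shallow")
})

test_that("circularity of squares equals pi/4 and the isoperimetric bound holds", {
  sq <- polyline3d(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                   closed = TRUE)
  ci <- circularity_index(list(sq, sq), normal = c(0, 0, 1))
  expect_equal(ci$ci, pi / 4, tolerance = 1e-9)
  # random closed curves respect 4 pi A / Pe^2 <= 1
  set.seed(21)
  for (k in 1:5) {
    th <- seq(0, 2 * pi, length.out = 129)[-129]
    r <- 1 + 0.3 * cos(2 * th + stats::runif(1, 0, pi)) +
      0.1 * cos(5 * th + stats::runif(1, 0, pi))
    cv <- polyline3d(cbind(r * cos(th), r * sin(th), 0), closed = TRUE)
    ci <- circularity_index(list(cv), normal = c(0, 0, 1))
    expect_lte(ci$per_curve$ratio, 1 + 1e-6)
  }
})

test_that("circularity index is invariant under rigid motion and uniform scaling", {
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  r <- 1 + 0.25 * cos(2 * th) + 0.05 * cos(4 * th)
  cv <- polyline3d(cbind(r * cos(th), r * sin(th), 0), closed = TRUE)
  ci0 <- circularity_index(list(cv), normal = c(0, 0, 1))$ci
  R <- fpdgen:::rot_xyz(c(0.3, 1.1, 2.0))
  cv2 <- apply_rigid(cv, R, c(4, -2, 7))
  cv2$points <- cv2$points * 3.7
  ci1 <- circularity_index(list(cv2), normal = as.numeric(R %*% c(0, 0, 1)))$ci
  expect_equal(ci1, ci0, tolerance = 1e-9)
})

test_that("the 0.97 threshold rule is inclusive and mixed readings fall to tooth", {
  expect_equal(classify_support(0.997, 0.997), "implant")
  expect_equal(classify_support(0.922, 0.922), "tooth")
  expect_equal(classify_support(0.97, 0.98), "implant")
  expect_equal(classify_support(0.9699, 0.98) |> suppressWarnings(), "tooth")
  expect_warning(classify_support(0.92, 0.99), "mixed")
})

test_that("fixtures classify to their construction type across seeds", {
  for (seed in 0:9) {
    fx <- make_fpd_fixture("tooth", seed = seed)
    det <- detect_support(fx$fpd)
    expect_equal(det$support_type, "tooth", label = paste("tooth seed", seed))
    expect_lt(det$ci_distal$ci, 0.97)
    expect_gt(det$ci_distal$ci, 0.85)
  }
  for (seed in 0:9) {
    fx <- make_fpd_fixture("implant", seed = seed)
    det <- detect_support(fx$fpd)
    expect_equal(det$support_type, "implant",
                 label = paste("implant seed", seed))
    expect_gte(det$ci_distal$ci, 0.99)
    expect_gte(det$ci_mesial$ci, 0.99)
  }
})

test_that("implant fixture lumens retain a deep stack of closed sections", {
  fx <- make_fpd_fixture("implant", seed = 0)
  al <- align_fpd(fx$fpd)
  det <- detect_support(al$fpd)
  expect_gte(nrow(det$ci_distal$per_curve), 30)
})
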
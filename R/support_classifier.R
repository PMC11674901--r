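# Support-type detection: slice each lumen with equally spaced planes
# along the gingival-occlusal box line, keep closed section curves,
# compute the circularity index 4*pi*A/Pe^2 and classify.

#' Slice a lumen with equally spaced planes
#'
#' Generates `n_planes` planes perpendicular to the gingival-occlusal line
#' `l_p` (equally spaced, endpoints included), sections the lumen with
#' each, retains only closed intersection curves, and finally drops the
#' curves of the first and the last plane that produced any (guarding
#' against margin/apex artefacts).
#'
#' @param lumen an open lumen [trimesh].
#' @param l_p 2x3 matrix: gingival and occlusal box-face centres.
#' @param n_planes number of planes (default 100).
#' @return list of class `section_stack` with `curves`, their `normal` and
#'   `plane_positions` (parameter along `l_p`).
#' @export
section_lumen <- function(lumen, l_p, n_planes = 100) {
  if (n_planes < 3) stop("need at least 3 planes")
  a <- l_p[1, ]; b <- l_p[2, ]
  nrm <- (b - a) / sqrt(sum((b - a)^2))
  ts <- seq(0, 1, length.out = n_planes)
  per_plane <- vector("list", n_planes)
  for (i in seq_len(n_planes)) {
    orig <- a + ts[i] * (b - a)
    cs <- section_with_plane(lumen, frame_from_zx(orig, nrm,
                                                  pick_perp(nrm)))
    cs <- Filter(function(p) p$closed, cs)
    per_plane[[i]] <- cs
  }
  nonempty <- which(vapply(per_plane, length, 1L) > 0)
  if (length(nonempty) > 2) {
    per_plane[[nonempty[1]]] <- list()
    per_plane[[nonempty[length(nonempty)]]] <- list()
  }
  curves <- do.call(c, per_plane)
  pos <- rep(ts, vapply(per_plane, length, 1L))
  if (length(curves) < 3)
    stop("lumen too shallow to classify (fewer than 3 closed sections)")
  structure(list(curves = curves, normal = nrm, plane_positions = pos),
            class = "section_stack")
}

pick_perp <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a - sum(a * n) * n
}

#' Circularity index of a section stack
#'
#' For each retained closed curve the ratio \eqn{4 \pi A / Pe^2} is
#' computed on the curve resampled to `n_resample` points and projected
#' into its section plane (shoelace area, polygonal perimeter); the CI is
#' the arithmetic mean over the curves.  The ratio is 1 for a circle and
#' decreases for irregular shapes (isoperimetric inequality), and is
#' invariant under rigid motion and uniform scaling.  Self-intersecting
#' section polygons are excluded with a warning.
#'
#' @param stack a `section_stack` (or plain list of closed [polyline3d]
#'   with a `normal` attribute supplied via `normal`).
#' @param n_resample resampling density per curve.
#' @param normal section-plane normal when `stack` is a plain list.
#' @return list of class `ci_report` with `ci` and a `per_curve` data
#'   frame (area, perimeter, ratio).
#' @export
circularity_index <- function(stack, n_resample = 256, normal = NULL) {
  if (inherits(stack, "section_stack")) {
    curves <- stack$curves
    nrm <- stack$normal
  } else {
    curves <- stack
    nrm <- normal
    if (is.null(nrm)) stop("supply the section-plane normal")
  }
  if (length(curves) < 1) stop("no curves to evaluate")
  area <- per <- ratio <- numeric(length(curves))
  keep <- logical(length(curves))
  for (i in seq_along(curves)) {
    rc <- resample_polyline(curves[[i]], n_resample)
    if (polygon_self_intersects(rc, nrm)) {
      keep[i] <- FALSE
      next
    }
    ap <- polygon_area_perimeter(rc, nrm)
    area[i] <- ap$area; per[i] <- ap$perimeter
    ratio[i] <- 4 * pi * ap$area / ap$perimeter^2
    keep[i] <- TRUE
  }
  if (any(!keep))
    warning(sum(!keep), " self-intersecting section curve(s) excluded")
  if (!any(keep)) stop("no valid section curves")
  structure(list(ci = mean(ratio[keep]),
                 per_curve = data.frame(area = area[keep],
                                        perimeter = per[keep],
                                        ratio = ratio[keep])),
            class = "ci_report")
}

# 2D segment-pair self-intersection test on the projected polygon
polygon_self_intersects <- function(poly, normal) {
  p <- poly$points
  nrm <- normal / sqrt(sum(normal^2))
  a <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * nrm) * nrm; u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2], nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  x <- as.numeric(p %*% u); y <- as.numeric(p %*% v)
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  # coarse sweep: compare each segment against all non-adjacent segments
  # using vectorised orientation tests on a subsample for speed
  idx <- if (n > 96) round(seq(1, n, length.out = 96)) else seq_len(n)
  xs <- x[idx]; ys <- y[idx]
  xe <- x2[idx]; ye <- y2[idx]
  m <- length(idx)
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(m - 2)) {
    j <- (i + 2):m
    if (i == 1) j <- j[j != m]
    d1 <- cross2(xe[i] - xs[i], ye[i] - ys[i], xs[j] - xs[i], ys[j] - ys[i])
    d2 <- cross2(xe[i] - xs[i], ye[i] - ys[i], xe[j] - xs[i], ye[j] - ys[i])
    d3 <- cross2(xe[j] - xs[j], ye[j] - ys[j], xs[i] - xs[j], ys[i] - ys[j])
    d4 <- cross2(xe[j] - xs[j], ye[j] - ys[j], xe[i] - xs[j], ye[i] - ys[j])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Classify the support type from the two lumen CI values
#'
#' A CI in `[0.97, 1]` (inclusive) on both sides indicates implant
#' support; anything else is tooth support.  Mixed readings (one side in
#' range, one not) classify as tooth with a warning.
#'
#' @param ci_distal,ci_mesial circularity indices (scalars or
#'   `ci_report`s).
#' @param threshold lower CI bound for implant support.
#' @return `"implant"` or `"tooth"`.
#' @export
classify_support <- function(ci_distal, ci_mesial, threshold = 0.97) {
  cd <- if (inherits(ci_distal, "ci_report")) ci_distal$ci else ci_distal
  cm <- if (inherits(ci_mesial, "ci_report")) ci_mesial$ci else ci_mesial
  slack <- 1e-6
  in_range <- function(x) x >= threshold & x <= 1 + slack
  if (in_range(cd) && in_range(cm)) return("implant")
  if (xor(in_range(cd), in_range(cm)))
    warning("mixed support indication (CI ", signif(cd, 3), " / ",
            signif(cm, 3), "); classified as tooth")
  "tooth"
}

#' Detect the support type of an aligned FPD
#'
#' Runs the full detection step: bounding box, gingival-occlusal line,
#' 100-plane sectioning of both lumens, circularity index and
#' classification.
#'
#' @param fpd an [fpd_model] (aligned or not; the step only uses its own
#'   box line).
#' @param n_planes planes along the gingival-occlusal line.
#' @return list with `support_type`, `ci_distal`, `ci_mesial` (reports)
#'   and the section stacks.
#' @export
detect_support <- function(fpd, n_planes = 100) {
  lm <- extract_landmarks(fpd)
  box <- min_oriented_bounding_box(fpd$merged)
  gf <- find_gingival_face(box, lm$p_md)
  l_p <- rbind(gf$centres[gf$gingival, ], gf$centres[gf$occlusal, ])
  std <- section_lumen(fpd$distal, l_p, n_planes)
  stm <- section_lumen(fpd$mesial, l_p, n_planes)
  cid <- circularity_index(std)
  cim <- circularity_index(stm)
  list(support_type = classify_support(cid, cim),
       ci_distal = cid, ci_mesial = cim,
       stack_distal = std, stack_mesial = stm)
}
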
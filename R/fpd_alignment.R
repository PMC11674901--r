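#' Labeled 4-unit FPD model
#'
#' Bundles the three labeled sub-meshes of a scanned (or synthetic) 4-unit
#' fixed partial denture: the external surface and the two open lumen
#' surfaces (distal = second molar, mesial = first premolar).
#'
#' @param surface,distal,mesial [trimesh] parts.
#' @return object of class `fpd_model` with a `merged` mesh.
#' @export
fpd_model <- function(surface, distal, mesial) {
  if (is.null(distal) || is.null(mesial) || is.null(surface))
    stop("fpd model needs surface, distal and mesial parts")
  structure(list(surface = surface, distal = distal, mesial = mesial,
                 merged = merge_meshes(list(surface, distal, mesial),
                                       name = "fpd")),
            class = "fpd_model")
}

#' Read an FPD from a multi-solid STL file
#'
#' Expects solids named `surface`, `distal` and `mesial`.
#' @param path STL file.
#' @return an [fpd_model].
#' @export
read_fpd_stl <- function(path) {
  parts <- read_stl(path)
  need <- c("surface", "distal", "mesial")
  if (!all(need %in% names(parts)))
    stop("STL must contain solids named ", paste(need, collapse = ", "),
         "; found: ", paste(names(parts), collapse = ", "))
  fpd_model(parts$surface, parts$distal, parts$mesial)
}

#' Write an FPD to a multi-solid STL file
#' @param fpd an [fpd_model]; @param path output file.
#' @return `path`, invisibly.
#' @export
write_fpd_stl <- function(fpd, path) {
  write_stl(list(surface = fpd$surface, distal = fpd$distal,
                 mesial = fpd$mesial), path)
}

lumen_margin_loop <- function(lumen, side = "lumen") {
  loops <- naked_edge_loops(lumen)
  if (length(loops) == 0)
    stop(side, " lumen must be open (watertight mesh has no margin curve)")
  lens <- vapply(loops, polyline_length, 1)
  loops[[which.max(lens)]]
}

#' Extract lumen landmarks of an FPD
#'
#' Finds the margin (boundary) curve of each lumen, its centre point (mean
#' of the arc-length-resampled curve), the mesiodistal line between the two
#' centres and its midpoint.
#'
#' @param fpd an [fpd_model].
#' @return list of class `fpd_landmarks` with `p_distal`, `p_mesial`,
#'   `line_md` (2x3 matrix), `p_md`, and the margin curves.
#' @export
extract_landmarks <- function(fpd) {
  c_distal <- lumen_margin_loop(fpd$distal, "distal")
  c_mesial <- lumen_margin_loop(fpd$mesial, "mesial")
  p_distal <- polyline_centre(c_distal)
  p_mesial <- polyline_centre(c_mesial)
  structure(list(p_distal = p_distal, p_mesial = p_mesial,
                 line_md = rbind(p_distal, p_mesial),
                 p_md = (p_distal + p_mesial) / 2,
                 c_distal = c_distal, c_mesial = c_mesial),
            class = "fpd_landmarks")
}

#' Identify the gingival face of the FPD bounding box
#'
#' The gingival face is the box face whose centre is nearest the midpoint
#' of the mesiodistal line (the lumens open gingivally); the opposite face
#' is occlusal.  Ties resolve to the lowest face index.
#'
#' @param box an [oriented_box].
#' @param p_md the mesiodistal midpoint.
#' @return list with `gingival` and `occlusal` face ids (1..6, see
#'   [box_faces]) and the face centres.
#' @export
find_gingival_face <- function(box, p_md) {
  fc <- box_faces(box)
  d <- sqrt(rowSums((fc$centres -
                       matrix(p_md, 6, 3, byrow = TRUE))^2))
  g <- which(d <= min(d) + 1e-12)[1]
  opp <- c(2, 1, 4, 3, 6, 5)
  list(gingival = g, occlusal = opp[g],
       centres = fc$centres, normals = fc$normals)
}

#' Build the FPD local frame
#'
#' Origin at the distal lumen centre; z axis normal to the gingival face
#' plane pointing occlusally; x axis along the mesiodistal line,
#' orthogonalised against z; y completes the right-handed triad.  When the
#' merged mesh is supplied, the gingival normal is refined by a principal
#' plane fit to the vertices lying on the gingival box face, which makes
#' the frame reproducible under rigid motion of the input.
#'
#' @param landmarks an [fpd_landmarks].
#' @param box the minimal [oriented_box] of the merged mesh.
#' @param mesh optional merged [trimesh] for the plane refinement.
#' @return a [frame3d].
#' @export
build_fpd_frame <- function(landmarks, box, mesh = NULL) {
  gf <- find_gingival_face(box, landmarks$p_md)
  n_g <- gf$normals[gf$gingival, ]           # outward (gingival) direction
  if (!is.null(mesh)) {
    # refine against the mesh itself: iterate a support-plane fit so the
    # result does not inherit the numerical tilt of the bounding box
    n_fit <- n_g
    for (iter in 1:3) {
      h <- as.numeric(mesh$vertices %*% n_fit)
      sel <- h > max(h) - 0.15
      if (sum(sel) < 16) break
      P <- mesh$vertices[sel, , drop = FALSE]
      ev <- eigen(stats::cov(P), symmetric = TRUE)
      cand <- ev$vectors[, 3]
      if (sum(cand * n_fit) < 0) cand <- -cand
      n_fit <- cand
    }
    # only adopt the fit when it agrees with the box normal
    if (sum(n_fit * n_g) > 0.98) n_g <- n_fit
  }
  z_ax <- -n_g                               # occlusal direction
  x_hint <- landmarks$p_mesial - landmarks$p_distal
  frame_from_zx(landmarks$p_distal, z_ax, x_hint)
}

#' Align an FPD to the global frame
#'
#' Applies the rigid motion carrying `frame` onto the global frame to all
#' three sub-meshes (and rebuilds the merged mesh).  After alignment the
#' distal lumen centre is at the origin, the mesial centre lies on the
#' +x axis (y = 0) and +z is occlusal.
#'
#' @param fpd an [fpd_model].
#' @param frame the FPD local [frame3d] (see [build_fpd_frame]).
#' @return the aligned [fpd_model].
#' @export
align_to_global <- function(fpd, frame) {
  gl <- frame3d()
  fpd_model(transform_to_frame(fpd$surface, frame, gl),
            transform_to_frame(fpd$distal, frame, gl),
            transform_to_frame(fpd$mesial, frame, gl))
}

#' Full FPD alignment step
#'
#' Landmarks, minimal bounding box, gingival-face detection, frame
#' construction and rigid alignment in one call.
#'
#' @param fpd an [fpd_model].
#' @return list with the aligned `fpd`, its recomputed `landmarks`, the
#'   local `frame` of the input pose, and the gingival `face` report.
#' @export
align_fpd <- function(fpd) {
  lm <- extract_landmarks(fpd)
  box <- min_oriented_bounding_box(fpd$merged)
  frame <- build_fpd_frame(lm, box, fpd$merged)
  aligned <- align_to_global(fpd, frame)
  list(fpd = aligned, landmarks = extract_landmarks(aligned), frame = frame,
       face = find_gingival_face(box, lm$p_md))
}
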
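# End-to-end case runner and solver-ready export.

#' Run the full support-generation pipeline on synthetic fixtures
#'
#' Fixture generation, alignment, support-type detection, support
#' generation, insertion into a layered bone segment, crestal defect
#' carving and PDL trimming, mirroring the study grid (support type x
#' bone quality x bone-loss depth).
#'
#' @param support_type `"tooth"` or `"implant"` (fixture variant; the
#'   pipeline still detects the type itself and stops on a mismatch).
#' @param quality Misch bone quality `"D1"`..`"D4"`.
#' @param depth bone-loss depth (mm).
#' @param seed fixture seed.
#' @param d_bone crest gap (mm).
#' @param tooth,implant parameter sets.
#' @return list of class `fpd_case` with the aligned FPD, detection
#'   report, placed `parts`, the post-defect `bone`, frames and metadata.
#' @export
run_case <- function(support_type = c("tooth", "implant"), quality = "D1",
                     depth = 0, seed = 0, d_bone = 2.8,
                     tooth = tooth_params(), implant = implant_params()) {
  support_type <- match.arg(support_type)
  fx <- make_fpd_fixture(support_type, seed = seed)
  al <- align_fpd(fx$fpd)
  det <- detect_support(al$fpd)
  if (det$support_type != support_type)
    stop("detected support type '", det$support_type,
         "' does not match the fixture variant")
  parts <- if (det$support_type == "tooth")
    generate_tooth_support(al, tooth)
  else
    generate_implant_support(al, implant)
  span <- sqrt(sum((al$landmarks$p_mesial - al$landmarks$p_distal)^2))
  bone <- make_bone_fixture(quality)
  bf <- build_bone_frame(bone, span)
  assembly <- c(list(surface = al$fpd$surface, distal = al$fpd$distal,
                     mesial = al$fpd$mesial), parts)
  placed <- place_assembly(assembly, frame3d(), bf, d_bone = d_bone,
                           bone = bone)
  cavity_parts <- if (det$support_type == "tooth")
    placed[c("pdl_47", "pdl_44")]
  else placed[c("implant_distal", "implant_mesial")]
  bone <- subtract_assembly(bone, cavity_parts)
  sites <- c(bf$p_distal[1], bf$p_mesial[1])
  bone <- carve_defect(bone, defect_spec(depth, sites = sites))
  if (det$support_type == "tooth") {
    placed$pdl_47 <- trim_pdl(placed$pdl_47, bone)
    placed$pdl_44 <- trim_pdl(placed$pdl_44, bone)
  }
  structure(list(support_type = det$support_type, quality = quality,
                 depth = depth, seed = seed, d_bone = d_bone,
                 aligned = al, detection = det, parts = placed,
                 bone = bone, bone_frame = bf, span = span),
            class = "fpd_case")
}

#' @export
print.fpd_case <- function(x, ...) {
  cat(sprintf("<fpd_case %s support, %s bone, %.1f mm bone loss: %d parts>\n",
              x$support_type, x$quality, x$depth, length(x$parts)))
  invisible(x)
}

case_material_labels <- function(case) {
  base <- c(surface = "fpd", distal = "fpd", mesial = "fpd")
  lab <- vapply(names(case$parts), function(nm) {
    if (nm %in% names(base)) return(base[[nm]])
    if (startsWith(nm, "cement")) return("cement")
    if (startsWith(nm, "tooth")) return("abutment_tooth")
    if (startsWith(nm, "pdl")) return("pdl_ogden")
    if (startsWith(nm, "abutment")) return("abutment")
    if (startsWith(nm, "implant")) return("implant")
    if (startsWith(nm, "screw")) return("implant_screw")
    "unknown"
  }, "")
  lab
}

#' Export a solver-ready case
#'
#' Writes one STL per part plus the bone layers, and an `assembly.json`
#' manifest: part files, material labels (with the elastic registry and
#' the Ogden PDL parameters), bone quality and graded-zone data, bonded
#' interface pairs, and the boundary-condition description used by the
#' downstream structural analysis (fixed base, frictionless mesiodistal
#' end faces, 105 N spread over three occlusal patches at the middle
#' connector).
#'
#' @param case an `fpd_case` from [run_case].
#' @param dir output directory (created if needed).
#' @return path of the manifest, invisibly.
#' @export
export_assembly <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- case_material_labels(case)
  files <- character(0)
  for (nm in names(case$parts)) {
    f <- file.path(dir, paste0(nm, ".stl"))
    write_stl(stats::setNames(list(case$parts[[nm]]), nm), f)
    files[nm] <- basename(f)
  }
  for (nm in c("outer", "cortical_interface", "transition_interface")) {
    f <- file.path(dir, paste0("bone_", nm, ".stl"))
    m <- case$bone[[nm]]
    # the remeshed bone can be large; binary keeps the export compact
    if (nrow(m$faces) > 2e5) write_stl_binary(m, f)
    else write_stl(stats::setNames(list(m), paste0("bone_", nm)), f)
    files[paste0("bone_", nm)] <- basename(f)
  }
  q <- bone_quality(case$quality)
  mats <- lapply(unique(lab), function(l) {
    if (l == "pdl_ogden") {
      op <- ogden_params()
      list(model = "ogden1", mu1_mpa = op$mu1, alpha1 = op$alpha1,
           d1 = op$d1)
    } else {
      m <- lookup_material(l)
      list(model = "linear_elastic", youngs_modulus_gpa = m$youngs_modulus,
           poisson_ratio = m$poisson_ratio, material = m$material)
    }
  })
  names(mats) <- unique(lab)
  bonded <- list()
  pn <- names(case$parts)
  add_pair <- function(a, b) {
    if (a %in% pn && b %in% pn)
      bonded[[length(bonded) + 1]] <<- c(a, b)
  }
  for (side in c("distal", "mesial")) {
    add_pair(side, paste0("cement_", side))
    add_pair(paste0("cement_", side),
             if (case$support_type == "tooth")
               if (side == "distal") "tooth_47" else "tooth_44"
             else paste0("abutment_", side))
    if (case$support_type == "implant") {
      add_pair(paste0("abutment_", side), paste0("implant_", side))
      add_pair(paste0("abutment_", side), paste0("screw_", side))
      add_pair(paste0("implant_", side), paste0("screw_", side))
    } else {
      tooth <- if (side == "distal") "tooth_47" else "tooth_44"
      pdl <- if (side == "distal") "pdl_47" else "pdl_44"
      add_pair(tooth, pdl)
    }
  }
  manifest <- list(
    case = list(support_type = case$support_type, bone_quality = case$quality,
                bone_loss_depth_mm = case$depth, d_bone_mm = case$d_bone,
                span_mm = case$span, seed = case$seed),
    parts = lapply(names(files), function(nm)
      list(name = nm, file = files[[nm]],
           material = if (nm %in% names(lab)) lab[[nm]] else
             if (startsWith(nm, "bone_outer")) "cortical_bone" else
               "bone_layer_interface")),
    materials = mats,
    bone = list(quality = q$label, cortical_thickness_mm = q$cortical_thickness,
                transition_thickness_mm = q$transition_thickness,
                e_cortical_gpa = q$e_cortical,
                e_cancellous_gpa = q$e_cancellous,
                graded_zone = "linear between cortical and cancellous moduli"),
    bonded_interfaces = bonded,
    boundary_conditions = list(
      fixed = "lower bone surface, all translations",
      frictionless = "mesial and distal bone end faces",
      load = list(force_n = 105,
                  description = paste("applied on three occlusal contact",
                                      "patches near the middle connector,",
                                      "parallel to the support axes"))))
  mf <- file.path(dir, "assembly.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mf)
}
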
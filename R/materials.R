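# Material data and constitutive models: elastic registry, Misch bone
# qualities with graded cortical/cancellous transition, first-order Ogden
# periodontal ligament.

material_registry_internal <- function() {
  reg <- list(
    implant        = list(material = "titanium_grade4", E = 104.5, nu = 0.37),
    abutment       = list(material = "titanium_grade4", E = 104.5, nu = 0.37),
    implant_screw  = list(material = "titanium_grade5", E = 114.0, nu = 0.33),
    cement         = list(material = "glass_ionomer_cement", E = 15.9,
                          nu = 0.33),
    abutment_tooth = list(material = "polyurethane", E = 3.525, nu = 0.33),
    fpd            = list(material = "zirconia", E = 210, nu = 0.27),
    cortical_bone  = list(material = "cortical_bone", E = 13.7, nu = 0.3),
    cancellous_bone_d1 = list(material = "cancellous_bone", E = 9.5, nu = 0.3),
    cancellous_bone_d2 = list(material = "cancellous_bone", E = 5.5, nu = 0.3),
    cancellous_bone_d3 = list(material = "cancellous_bone", E = 1.6, nu = 0.3),
    cancellous_bone_d4 = list(material = "cancellous_bone", E = 0.69,
                              nu = 0.3))
  # material-name aliases resolve to a representative component entry
  alias <- c(titanium_grade4 = "implant", titanium_grade5 = "implant_screw",
             glass_ionomer_cement = "cement", polyurethane = "abutment_tooth",
             zirconia = "fpd", zirconia_fpd = "fpd",
             cement_layer = "cement")
  list(reg = reg, alias = alias)
}

#' Look up elastic constants of a model component
#'
#' Registry of the component materials used in the downstream structural
#' model: titanium implant hardware, glass-ionomer cement, polyurethane
#' abutment tooth, zirconia FPD and cortical/cancellous bone.  Both
#' component keys (`"implant"`, `"cement"`, ...) and material aliases
#' (`"titanium_grade4"`, `"zirconia_fpd"`, ...) resolve.
#'
#' @param name component or material name (snake_case).
#' @return list with `name`, `material`, `youngs_modulus` (GPa),
#'   `poisson_ratio`.
#' @export
lookup_material <- function(name) {
  r <- material_registry_internal()
  key <- tolower(name)
  if (!is.null(r$alias[key]) && !is.na(r$alias[key])) key <- r$alias[[key]]
  if (is.null(r$reg[[key]]))
    stop("unknown material '", name, "'; known: ",
         paste(sort(unique(c(names(r$reg), names(r$alias)))), collapse = ", "))
  e <- r$reg[[key]]
  list(name = key, material = e$material, youngs_modulus = e$E,
       poisson_ratio = e$nu)
}

#' Misch bone-quality specification
#'
#' Cortical thickness decreases from 2.5 mm (D1) to 1.0 mm (D4) while the
#' cortical Young's modulus stays at 13.7 GPa; the cancellous modulus drops
#' from 9.5 GPa (D1) to 0.69 GPa (D4).  A 0.29 mm graded transition zone
#' separates the layers.
#'
#' @param label one of `"D1"`, `"D2"`, `"D3"`, `"D4"`.
#' @return list with `label`, `cortical_thickness` (mm), `e_cortical`,
#'   `e_cancellous` (GPa), `transition_thickness` (mm), `poisson_ratio`.
#' @export
bone_quality <- function(label) {
  tab <- list(D1 = c(2.5, 9.5), D2 = c(2.0, 5.5), D3 = c(1.5, 1.6),
              D4 = c(1.0, 0.69))
  label <- toupper(label)
  if (is.null(tab[[label]]))
    stop("unknown bone quality '", label, "'; use D1, D2, D3 or D4")
  v <- tab[[label]]
  list(label = label, cortical_thickness = v[1], e_cortical = 13.7,
       e_cancellous = v[2], transition_thickness = 0.29, poisson_ratio = 0.3)
}

#' Graded Young's modulus across the cortical/cancellous transition
#'
#' Constant 13.7 GPa up to the cortical/transition interface, linear over
#' the 0.29 mm transition zone, constant at the quality-specific cancellous
#' value beyond it; continuous everywhere.
#'
#' @param z depth past the cortical/transition interface (mm); vectorised.
#' @param spec a [bone_quality] spec (or quality label).
#' @return Young's modulus in GPa.
#' @export
graded_modulus <- function(z, spec) {
  if (is.character(spec)) spec <- bone_quality(spec)
  tw <- spec$transition_thickness
  e0 <- spec$e_cortical; e1 <- spec$e_cancellous
  frac <- pmin(pmax(z / tw, 0), 1)
  # convex combination: exact at both endpoints
  e0 * (1 - frac) + e1 * frac
}

#' First-order Ogden parameters of the periodontal ligament
#' @param mu1 shear-like modulus (MPa); @param alpha1 exponent;
#' @param d1 inverse bulk parameter (1/MPa); 0 means incompressible.
#' @return list of class `ogden_params`.
#' @export
ogden_params <- function(mu1 = 0.006, alpha1 = 29.8, d1 = 0.0) {
  if (mu1 * alpha1 <= 0) stop("mu1 * alpha1 must be positive")
  structure(list(mu1 = mu1, alpha1 = alpha1, d1 = d1), class = "ogden_params")
}

# strain energy along the incompressible uniaxial path
# (lambda, lambda^-1/2, lambda^-1/2); classical Ogden form
# W = (mu1/alpha1) (l1^a + l2^a + l3^a - 3).
ogden_energy_uniaxial <- function(stretch, p = ogden_params()) {
  a <- p$alpha1
  (p$mu1 / a) * (stretch^a + 2 * stretch^(-a / 2) - 3)
}

#' Uniaxial Cauchy stress of the incompressible first-order Ogden model
#'
#' Along the incompressible uniaxial path the Cauchy stress is
#' \eqn{\sigma(\lambda) = \mu_1 (\lambda^{\alpha_1} -
#' \lambda^{-\alpha_1/2})}: zero at \eqn{\lambda = 1}, strictly increasing,
#' with small-strain Young's modulus \eqn{3 \mu_1 \alpha_1 / 2}.
#'
#' @param stretch uniaxial stretch \eqn{\lambda > 0}; vectorised.
#' @param p an [ogden_params] object.
#' @return Cauchy stress in MPa.
#' @export
ogden_uniaxial_stress <- function(stretch, p = ogden_params()) {
  if (any(stretch <= 0)) stop("stretch must be positive")
  a <- p$alpha1
  p$mu1 * (stretch^a - stretch^(-a / 2))
}
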
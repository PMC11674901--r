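# Elastic registry, Misch qualities, graded transition, Ogden PDL.

test_that("the elastic registry returns the published constants", {
  z <- lookup_material("zirconia_fpd")
  expect_equal(z$youngs_modulus, 210)
  expect_equal(z$poisson_ratio, 0.27)
  t4 <- lookup_material("titanium_grade4")
  expect_equal(t4$youngs_modulus, 104.5)
  expect_equal(t4$poisson_ratio, 0.37)
  expect_equal(lookup_material("implant_screw")$youngs_modulus, 114.0)
  expect_equal(lookup_material("cement")$youngs_modulus, 15.9)
  expect_equal(lookup_material("abutment_tooth")$youngs_modulus, 3.525)
  expect_equal(lookup_material("cortical_bone")$youngs_modulus, 13.7)
  expect_error(lookup_material("unobtainium"), "known")
})

test_that("Misch qualities step down monotonically in thickness and stiffness", {
  qs <- lapply(c("D1", "D2", "D3", "D4"), bone_quality)
  th <- vapply(qs, function(q) q$cortical_thickness, 1)
  ec <- vapply(qs, function(q) q$e_cancellous, 1)
  expect_equal(th, c(2.5, 2.0, 1.5, 1.0))
  expect_equal(ec, c(9.5, 5.5, 1.6, 0.69))
  expect_true(all(diff(th) < 0) && all(diff(ec) < 0))
  expect_true(all(vapply(qs, function(q) q$e_cortical, 1) == 13.7))
  expect_true(all(vapply(qs, function(q) q$transition_thickness, 1) == 0.29))
  expect_error(bone_quality("D5"), "D1")
})

test_that("graded modulus is continuous, monotone and hits both endpoints", {
  for (q in c("D1", "D2", "D3", "D4")) {
    spec <- bone_quality(q)
    expect_equal(graded_modulus(0, spec), 13.7)
    expect_equal(graded_modulus(-1, spec), 13.7)
    expect_equal(graded_modulus(0.29, spec), spec$e_cancellous)
    expect_equal(graded_modulus(1, spec), spec$e_cancellous)
    z <- seq(-0.1, 0.5, by = 1e-3)
    e <- graded_modulus(z, spec)
    expect_true(all(diff(e) <= 1e-12))      # non-increasing
    expect_lt(max(abs(diff(e))), 0.06)      # no jumps
  }
  expect_equal(graded_modulus(0.145, "D3"), (13.7 + 1.6) / 2)
})

test_that("Ogden uniaxial stress is stress-free at lambda 1 and energy-consistent", {
  p <- ogden_params()
  expect_equal(ogden_uniaxial_stress(1, p), 0)
  lam <- seq(0.5, 2, by = 0.01)
  sig <- ogden_uniaxial_stress(lam, p)
  expect_true(all(diff(sig) > 0))
  # Cauchy stress equals lambda * dW/dlambda along the incompressible path
  hh <- 1e-6
  for (l in c(0.7, 0.95, 1.1, 1.5)) {
    dW <- (fpdgen:::ogden_energy_uniaxial(l + hh, p) -
             fpdgen:::ogden_energy_uniaxial(l - hh, p)) / (2 * hh)
    expect_equal(ogden_uniaxial_stress(l, p), l * dW,
                 tolerance = 1e-6 * max(abs(l * dW), 1e-12))
  }
  # small-strain tangent: E = 3 mu0 with mu0 = mu1 alpha1 / 2
  eps <- 1e-5
  E_tan <- ogden_uniaxial_stress(1 + eps, p) / eps
  expect_equal(E_tan, 3 * p$mu1 * p$alpha1 / 2, tolerance = 1e-3 * E_tan)
  # odd symmetry in log stretch to first order: the symmetric part decays
  # quadratically with the strain
  asym <- function(eps) abs(ogden_uniaxial_stress(exp(eps), p) +
                              ogden_uniaxial_stress(exp(-eps), p))
  expect_lt(asym(1e-4), 1e-7)
  expect_lt(asym(1e-5), 1e-9)
  expect_error(ogden_uniaxial_stress(-0.5), "positive")
  expect_error(ogden_params(mu1 = 0), "positive")
})
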
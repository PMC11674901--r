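# Lazily built, cached fixtures shared across test files (building the
# support parts once keeps the suite fast).

.cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.cache[[key]])) .cache[[key]] <- build()
  .cache[[key]]
}

tooth_aligned <- function() cached("tooth_aligned", function() {
  align_fpd(make_fpd_fixture("tooth", seed = 0)$fpd)
})

implant_aligned <- function() cached("implant_aligned", function() {
  align_fpd(make_fpd_fixture("implant", seed = 0)$fpd)
})

tooth_parts <- function() cached("tooth_parts", function() {
  generate_tooth_support(tooth_aligned())
})

implant_parts <- function() cached("implant_parts", function() {
  generate_implant_support(implant_aligned())
})

bone_d1 <- function() cached("bone_d1", function() make_bone_fixture("D1"))

expect_watertight <- function(mesh) {
  expect_true(is_watertight(mesh), label = paste0("watertight(", mesh$name, ")"))
}
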
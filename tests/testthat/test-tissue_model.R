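test_that("bundled mouse-head presets carry the tabulated optical parameters", {
  ex <- default_stack("excitation_785")
  expect_identical(ex$layers$name, c("skin", "skull", "csf", "cortex"))
  expect_equal(ex$layers$n, c(1.37, 1.454, 1.33, 1.368))
  expect_equal(ex$layers$mu_a, c(1.62, 0.087, 0.1, 0.087))
  expect_equal(ex$layers$mu_s, c(238.9, 162.7, 0, 76.2))
  expect_equal(ex$layers$g, c(0.9, 0.9, 1, 0.9))
  expect_equal(ex$layers$thickness[1:3], c(0.02, 0.01, 0.01))
  expect_equal(ex$z_boundaries[1:4], c(0, 0.02, 0.03, 0.04))

  em <- default_stack("emission_1100")
  expect_identical(em$layers$name[1], "air")
  expect_equal(em$layers[em$layers$name == "air", c("n", "mu_a", "mu_s", "g")],
               data.frame(n = 1, mu_a = 0.001, mu_s = 0, g = 1,
                          row.names = 1L))
  expect_equal(unlist(em$layers[em$layers$name == "skull",
                                c("n", "mu_a", "mu_s")], use.names = FALSE),
               c(1.45, 0.4, 135.6))
  expect_equal(em$layers$mu_a[em$layers$name == "skin"], 0.35)
  expect_equal(em$layers$mu_s[em$layers$name == "cortex"], 71.4)
  # air guard layer sits above the skin: z in [-0.01, 0]
  expect_equal(em$z_boundaries[1:2], c(-0.01, 0))
})

test_that("cross-wavelength scattering ratios match their rounded published forms", {
  ex <- default_stack("excitation_785")$layers
  em <- default_stack("emission_1100")$layers
  skull_ratio <- em$mu_s[em$name == "skull"] / ex$mu_s[ex$name == "skull"]
  expect_lt(abs(skull_ratio - 0.83) / 0.83, 0.01)   # "83%"
  skin_ratio <- ex$mu_s[ex$name == "skin"] / em$mu_s[em$name == "skin"]
  expect_lt(abs(skin_ratio - 1.4) / 1.4, 0.01)      # "1.4-fold"
})

test_that("layer and stack validation rejects unphysical inputs", {
  expect_error(layer("bad", n = 0.9, mu_a = 1, mu_s = 1, g = 0,
                     thickness = 0.1), "refractive")
  expect_error(layer("bad", n = 1.4, mu_a = -1, mu_s = 1, g = 0,
                     thickness = 0.1), "mu_a")
  expect_error(layer("bad", n = 1.4, mu_a = 1, mu_s = 1, g = 2,
                     thickness = 0.1), "anisotropy")
  expect_error(layer("bad", n = 1.4, mu_a = 1, mu_s = 1, g = 0,
                     thickness = 0), "thickness")
  # infinite thickness only for the bottom layer
  expect_error(layer_stack(rbind(
    layer("a", 1.4, 1, 1, 0, Inf), layer("b", 1.4, 1, 1, 0, 0.1))),
    "bottom")
  expect_silent(layer_stack(rbind(
    layer("a", 1.4, 1, 1, 0, 0.1), layer("b", 1.4, 1, 1, 0, Inf))))
  expect_error(default_stack("excitation_785", cortex_thickness = -1))
  expect_error(default_stack("infrared_9000"))
})

test_that("depth queries resolve exact boundaries to the layer below", {
  s <- default_stack("excitation_785")
  expect_equal(layer_at_depth(s, 0.01), 1)    # inside skin
  expect_equal(layer_at_depth(s, 0.025), 2)   # skin ends at 0.02
  expect_equal(layer_at_depth(s, 0.02), 2)    # boundary -> below
  expect_equal(layer_at_depth(s, 0.04), 4)    # CSF ends at 0.04 -> cortex
  expect_equal(layer_at_depth(s, s$z_boundaries[5]), 4)  # bottom edge
  expect_error(layer_at_depth(s, -0.001), "outside")
  expect_error(layer_at_depth(s, 99), "outside")
})

test_that("stack configs round-trip through YAML in both cm and mm", {
  s <- default_stack("emission_1100")
  for (units in c("cm", "mm")) {
    path <- withr::local_tempfile(fileext = ".yaml")
    save_stack(s, path, units = units)
    s2 <- load_stack(path)
    expect_equal(s2$layers, s$layers)
    expect_equal(s2$z_boundaries, s$z_boundaries)
    expect_identical(s2$wavelength_tag, s$wavelength_tag)
  }
})

test_that("bundled preset files equal the in-code defaults (mm conversion)", {
  p785 <- load_stack("mousehead_785")
  d785 <- default_stack("excitation_785")
  expect_equal(p785$layers, d785$layers)
  expect_equal(p785$z_boundaries, d785$z_boundaries)
  p1100 <- load_stack("mousehead_1100")
  expect_equal(p1100$layers, default_stack("emission_1100")$layers)
  # a 0.2 mm skin thickness in a mm file becomes 0.02 cm internally
  expect_equal(p785$layers$thickness[1], 0.02)
})

test_that("malformed stack configs are rejected with schema errors", {
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("units: mm", "layers:",
               "- {name: skin, n: 1.37, mu_a: -5, mu_s: 1, g: 0.9, thickness: 0.2}"),
             bad)
  expect_error(load_stack(bad), "mu_a")
  writeLines(c("units: furlongs", "layers: []"), bad)
  expect_error(load_stack(bad), "units")
  writeLines(c("units: mm", "layers:",
               "- {name: skin, n: 1.37, mu_s: 1, g: 0.9, thickness: 0.2}"),
             bad)
  expect_error(load_stack(bad), "missing")
  expect_error(load_stack("no_such_preset"), "preset")
})
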
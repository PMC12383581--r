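test_that("reference geometry reproduces the anatomical table and its nesting identities", {
  g <- default_geometry()
  expect_equal(g$total_height, 90)
  expect_equal(g$vertebra_body_height, 14)
  expect_equal(g$vertebra_ml_width, 24.5)
  expect_equal(g$vertebra_ap_width, 14)
  expect_equal(g$cavity_diameter, 12)
  expect_equal(g$disc_height, 4)
  expect_equal(g$fat_outer_diameter, 12)
  expect_equal(g$fat_thickness, 0.3)
  expect_equal(g$dura_outer_diameter, 11.4)
  expect_equal(g$dura_thickness, 0.2)
  expect_equal(g$csf_outer_diameter, 11)
  expect_equal(g$csf_thickness, 1)
  expect_equal(g$cord_diameter, 9)
  expect_equal(g$tumour_diameter, 7)
  expect_equal(g$tumour_height, 25)
  expect_equal(g$n_vertebrae, 5L)
  # layer nesting identities
  expect_equal(g$fat_outer_diameter - 2 * g$fat_thickness,
               g$dura_outer_diameter)
  expect_equal(g$dura_outer_diameter - 2 * g$dura_thickness,
               g$csf_outer_diameter)
  expect_equal(g$csf_outer_diameter - 2 * g$csf_thickness, g$cord_diameter)
  # summed part heights fit inside the segment with end-cap slack
  parts <- g$n_vertebrae * g$vertebra_body_height +
    (g$n_vertebrae - 1) * g$disc_height
  expect_equal(parts, 86)
  expect_lte(parts, g$total_height)
})

test_that("geometry validation rejects broken nesting and names the failing pair", {
  expect_error(geometry_config(dura_outer_diameter = 10),
               "dura_mater")
  expect_error(geometry_config(tumour_diameter = 9.5),
               "tumour")
  expect_error(geometry_config(tip_face_diameter = 8), "tip_face_diameter")
  expect_error(geometry_config(total_height = 50),
               "exceed total_height")
  expect_error(geometry_config(cord_diameter = -1), "positive")
})

test_that("random nested geometries satisfy the invariants and build valid models", {
  set.seed(42)
  for (i in 1:25) {
    g <- random_geometry()
    expect_s3_class(g, "cusa_geometry")
    expect_equal(g$csf_outer_diameter - 2 * g$csf_thickness, g$cord_diameter)
    m <- build_model(g)
    expect_equal(length(m$regions),
                 g$n_vertebrae + (g$n_vertebrae - 1) + 5)
    v <- model_volume(m)
    expect_true(all(v > 0))
  }
})

test_that("material registry matches the reference property table", {
  mats <- default_materials()
  expect_setequal(names(mats),
                  c("bone", "disc", "fat", "dura", "csf", "cord", "tumour"))
  expect_equal(mats$tumour$youngs_modulus, 1.8e-3)
  expect_equal(mats$tumour$poisson_ratio, 0.3)
  expect_equal(mats$csf$poisson_ratio, 0.4887)
  expect_equal(mats$csf$thermal_conductivity, 0.57)
  expect_equal(mats$bone$density, 0.131)
  expect_equal(mats$bone$youngs_modulus, 7600)
  expect_equal(mats$cord$youngs_modulus, 40.12e-3)
  expect_equal(mats$disc$heat_capacity, 3568)
  expect_equal(mats$fat$thermal_conductivity, 0.2)
  expect_equal(mats$dura$youngs_modulus, 31.5)
  for (m in mats) {
    expect_gt(m$thermal_conductivity, 0)
    expect_lt(m$poisson_ratio, 0.5)
    expect_gt(m$density, 0)
    expect_gt(m$heat_capacity, 0)
  }
  si <- material_si(mats$tumour)
  expect_equal(si$E, 1800)     # MPa -> Pa
  expect_equal(si$rho, 1075)   # g/cm^3 -> kg/m^3
})

test_that("device power maps linearly to amplitude with the transducer floor", {
  expect_equal(power_to_amplitude(60), 213)
  expect_equal(power_to_amplitude(100), 355)
  expect_equal(power_to_amplitude(20), 71)
  expect_equal(power_to_amplitude(5), 35)  # clamped at the transducer stroke
  expect_error(power_to_amplitude(0))
  expect_error(power_to_amplitude(120))
})

test_that("load cases validate the device envelope and presets carry published heat budgets", {
  lc <- load_case(70, 36)
  expect_equal(lc$amplitude, 35)
  expect_equal(lc$angular_frequency, 2 * pi * 36e3)
  expect_error(load_case(30, 36), "35-355")
  expect_error(load_case(70, 40), "23 or 36")
  p70 <- load_case_preset("paper-70um")
  p213 <- load_case_preset("paper-213um")
  expect_equal(p70$Q, 0.3907)
  expect_equal(p213$Q, 3.6579)
  expect_equal(p70$A, 6.5742e-4)
  expect_equal(p70$power_percent, 20)
  expect_equal(p213$displacement_pp, 213)
})

test_that("the labelled model resolves regions, tumour placement and named surfaces", {
  m <- build_model(default_geometry())
  expect_length(m$regions, 14)
  expect_setequal(m$regions,
                  c(paste0("vertebra_", 1:5), paste0("disc_", 1:4),
                    "epidural_fat", "dura_mater", "csf", "spinal_cord",
                    "tumour"))
  # tumour centred on the disc between vertebrae 2 and 3 (C4-C5)
  zb <- m$z_bands
  d2 <- zb[zb$region == "disc_2", ]
  expect_equal(m$tumour_centre[3], (d2$z0 + d2$z1) / 2)
  expect_equal(diff(m$tumour_z), 25)
  expect_equal(m$tip_centre[2], 3.5)
  # toy path is quick and single-vertebra
  t0 <- Sys.time()
  tm <- build_model(toy_geometry())
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_length(tm$regions, 6)
})

test_that("tumour surface area modes agree with closed forms and the published constant", {
  m <- build_model()
  r <- 3.5e-3; h <- 25e-3
  expect_equal(tumour_surface_area(m, "closed_form"),
               2 * pi * r^2 + 2 * pi * r * h)
  expect_equal(tumour_surface_area(m, "closed_form"), 6.2675e-4,
               tolerance = 1e-4)
  expect_equal(tumour_surface_area(m, "reference"), 6.5742e-4)
  # degenerate tumour height: area tends to the two caps
  md <- build_model(geometry_config(tumour_height = 1e-9))
  expect_equal(tumour_surface_area(md, "closed_form"), 2 * pi * r^2,
               tolerance = 1e-6)
  # the smoothed reference constant exceeds the sharp cylinder
  expect_gt(tumour_surface_area(m, "reference"),
            tumour_surface_area(m, "closed_form"))
})

test_that("configuration files round-trip exactly and the model exports JSON", {
  cfg <- simulation_config(h = 12.5, loss_factor = 0.07)
  cfg$materials$tumour <- material_properties(1.08, 2.1e-3, 0.31, 0.52, 3600)
  path <- tempfile(fileext = ".cfg")
  write_config(cfg, path)
  back <- read_config(path)
  expect_identical(unclass(back$geometry), unclass(cfg$geometry))
  expect_identical(back$materials$tumour, cfg$materials$tumour)
  expect_identical(back$h, cfg$h)
  expect_identical(back$loss_factor, cfg$loss_factor)
  expect_identical(back$sizing$tip_face_size, cfg$sizing$tip_face_size)
  js <- export_model_json(build_model(toy_geometry()))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$tip_radius_mm, 1)
  expect_equal(parsed$geometry$cord_diameter, 9)
})
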
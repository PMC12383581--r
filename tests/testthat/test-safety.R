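test_that("threshold construction enforces ordering", {
  th <- safety_thresholds()
  expect_equal(th$tolerable_max, 44)
  expect_equal(th$damage_threshold, 46)
  expect_equal(th$max_dwell, 1)
  expect_error(safety_thresholds(tolerable_max = 47))
  expect_error(safety_thresholds(max_dwell = 0))
})

test_that("safety evaluation flags, margins and recommendations are consistent", {
  tab <- data.frame(tissue = c("tumour", "cord", "csf"),
                    case1 = c(42.48, 41.94, 39.45))
  rep <- evaluate_safety(tab)
  expect_true(rep$pass)
  expect_equal(rep$margin, 46 - 42.48)
  expect_length(rep$flagged, 0)
  expect_match(rep$recommendation, "1 s")
  # a tissue above the damage threshold fails exactly that tissue
  tab2 <- data.frame(tissue = c("tumour", "cord"), case1 = c(47, 43.5))
  rep2 <- evaluate_safety(tab2)
  expect_false(rep2$pass)
  expect_equal(rep2$tissue[rep2$fail], "tumour")
  expect_lt(rep2$margin, 0)
  # between tolerable and damage -> warn only
  tab3 <- data.frame(tissue = "cord", case1 = 45)
  rep3 <- evaluate_safety(tab3)
  expect_true(rep3$pass)
  expect_equal(rep3$flagged, "cord")
  expect_error(evaluate_safety(data.frame(tissue = character(0))), "empty")
})

test_that("the pipeline is deterministic and internally consistent on the toy model", {
  ctx <- toy_ctx()
  r1 <- run_case(ctx, "paper-70um")
  r2 <- run_case(ctx, "paper-70um")
  expect_identical(r1$region_table, r2$region_table)
  expect_identical(r1$peak_strain, r2$peak_strain)
  expect_identical(r1$Q, r2$Q)
  # q = Q / A exactly, and matches flux_from_power
  expect_identical(r1$q, flux_from_power(r1$Q, r1$A)$q)
  # energy bookkeeping: injected power is q * tip-face area, not Q
  expect_equal(r1$injected_power_W, r1$q * r1$flux_area_m2,
               tolerance = 1e-12)
  expect_lt(r1$injected_power_W, r1$Q)
  # transient end stays below the steady maxima
  expect_true(all(r1$region_table$transient_end <=
                    r1$region_table$steady + 1e-9))
})

test_that("zero heat input leaves every tissue at 37 C and passes", {
  ctx <- toy_ctx()
  lc <- load_case_preset("paper-70um")
  lc$Q <- 0
  r <- run_case(ctx, lc, transient = FALSE)
  expect_equal(r$q, 0)
  expect_equal(unname(unlist(r$region_table$steady)),
               rep(37, nrow(r$region_table)), tolerance = 1e-10)
  expect_true(r$safety$pass)
  expect_length(r$safety$flagged, 0)
})

test_that("amplitude sweep reuses the pipeline consistently and scales monotonically", {
  ctx <- toy_ctx()
  sw <- sweep_amplitudes(ctx, c(70, 140, 213))
  expect_equal(nrow(sw), 3)
  # bit-identical to direct runs of the same load cases
  r70 <- run_case(ctx, load_case(70, 36), transient = FALSE)
  expect_identical(sw$q_W_m2[1], r70$q)
  expect_identical(sw$tumour_max_C[1],
                   r70$region_table$steady[r70$region_table$tissue ==
                                             "tumour"])
  expect_identical(sw$peak_strain[1], r70$peak_strain)
  # monotone flux and tumour maximum in amplitude
  expect_true(all(diff(sw$q_W_m2) > 0))
  expect_true(all(diff(sw$tumour_max_C) > 0))
  # quadratic flux law across the sweep
  expect_equal(sw$q_W_m2[3] / sw$q_W_m2[1], (213 / 70)^2, tolerance = 1e-12)
  # extrapolated damage-threshold crossing is reported and beyond 213 um
  cross <- attr(sw, "crossing_amplitude_um")
  expect_true(is.finite(cross))
  expect_gt(cross, 213)
})

test_that("stage failures propagate with the stage name", {
  cfg <- toy_config()
  cfg$materials$tumour <- NULL
  ctx <- simulation_context(cfg)
  expect_error(run_case(ctx, "paper-70um"), "stage '")
})

test_that("the command-line front end runs the toy report end to end", {
  script <- system.file("cli", "cusafem.R", package = "cusafem")
  expect_true(nzchar(script))
  out <- tempfile("cli_out")
  res <- system2("Rscript", c(script, "report", "--toy", "--out", out),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  expect_true(file.exists(file.path(out, "safety_table.csv")))
  js <- jsonlite::fromJSON(file.path(out, "safety_report.json"))
  expect_true(js$pass_70um)
  expect_true(js$pass_213um)
  tab <- utils::read.csv(file.path(out, "safety_table.csv"))
  expect_true(all(tab$max_T_213um >= tab$max_T_70um - 1e-9))
})
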
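# workload -> unshielded dose -> required transmission -> barrier thickness

test_that("the treatment-room worked example reproduces end to end", {
  w <- decay_corrected_workload(200, 4, 5, "Lu-177", apply_decay = FALSE)
  expect_equal(w$mci_hours, 4000)
  d <- unshielded_weekly_dose(w, 240)
  expect_equal(signif(d, 4), 120.3)
  tr <- required_transmission(d, limit_uGy = 20, occupancy = 1)
  expect_signif3(tr, 0.166)
  sc <- shielding_scenario("Lu-177", w, "lead", distance_cm = 240,
                           limit_uGy_per_week = 20, occupancy = 1)
  sol <- solve_barrier(sc)
  expect_signif3(sol$required_thickness_mm, 1.48)
  expect_length(sol$warnings, 0)
})

test_that("the extreme high-workload scenario needs sub-1% transmission and warns", {
  w <- workload("Lu-177", 18000, "300 mCi constantly present for 60 h/week")
  d <- unshielded_weekly_dose(w, 73.2)
  expect_equal(d, 18000 * 0.181 * 9.57e-3 / 73.2^2 * 1e6, tolerance = 1e-12)
  tr <- required_transmission(d, 20)
  expect_equal(signif(tr, 2), 0.0034)
  sc <- shielding_scenario("Lu-177", w, "lead", distance_cm = 73.2)
  expect_warning(sol <- solve_barrier(sc), "below 0.01")
  expect_true(any(grepl("scatter", sol$warnings)))
  expect_lt(sol$required_transmission, 0.01)
})

test_that("unshielded dose follows the inverse-square law and is linear in workload", {
  w <- workload("Tc-99m", 1000)
  d1 <- unshielded_weekly_dose(w, 100)
  expect_equal(unshielded_weekly_dose(w, 200), d1 / 4)
  w2 <- workload("Tc-99m", 2000)
  expect_equal(unshielded_weekly_dose(w2, 100), 2 * d1)
  expect_equal(unshielded_weekly_dose(workload("Tc-99m", 0), 100), 0)
  expect_error(unshielded_weekly_dose(w, 0), "> 0")
})

test_that("decay correction shrinks the workload by the session-averaged factor", {
  on <- decay_corrected_workload(200, 4, 5, "Lu-177", apply_decay = TRUE)
  lam <- log(2) / (6.65 * 24)
  expect_equal(on$mci_hours, 4000 * (1 - exp(-lam * 4)) / (lam * 4))
  expect_equal(round(on$mci_hours), 3965)
  expect_lt(on$mci_hours, 4000)
  # the factor tends to 1 for vanishing session length
  short <- decay_corrected_workload(200, 1e-6, 5, "Lu-177", apply_decay = TRUE)
  expect_equal(short$mci_hours, 200 * 1e-6 * 5, tolerance = 1e-6)
})

test_that("activity in GBq converts at exactly 37 MBq/mCi", {
  a <- decay_corrected_workload(activity_GBq = 7.4, hours_per_session = 4,
                                sessions_per_week = 5, nuclide = "Lu-177")
  b <- decay_corrected_workload(200, 4, 5, "Lu-177")
  expect_identical(a$mci_hours, b$mci_hours)
})

test_that("lower occupancy allows more transmission and a thinner barrier", {
  w <- workload("I-131", 5000)
  base <- shielding_scenario("I-131", w, "lead", distance_cm = 300,
                             occupancy = 1)
  fifth <- shielding_scenario("I-131", w, "lead", distance_cm = 300,
                              occupancy = "corridor")
  s1 <- solve_barrier(base)
  s5 <- solve_barrier(fifth)
  expect_equal(fifth$occupancy, 0.2)
  expect_gt(s5$required_transmission, s1$required_transmission)
  expect_lt(s5$required_thickness_mm, s1$required_thickness_mm)
})

test_that("no barrier is required when the limit is already met", {
  w <- workload("Lu-177", 4000)
  sc <- shielding_scenario("Lu-177", w, "lead", distance_cm = 240,
                           limit_uGy_per_week = 1000)
  sol <- solve_barrier(sc)
  expect_identical(sol$required_transmission, 1)
  expect_identical(sol$required_thickness_mm, 0)
})

test_that("solve_barrier is deterministic", {
  sc <- shielding_scenario("Lu-177", workload("Lu-177", 4000), "lead",
                           distance_cm = 240)
  a <- solve_barrier(sc)
  b <- solve_barrier(sc)
  a$log$timestamp <- b$log$timestamp <- NULL
  expect_identical(a[names(a) != "log"], b[names(b) != "log"])
})

test_that("composite barriers multiply per-layer transmissions", {
  expect_identical(composite_transmission(list(), "Tc-99m"), 1)
  single <- composite_transmission(list(list(material = "lead",
                                             thickness_mm = 1)), "Tc-99m")
  p <- get_archer_params("Tc-99m", "lead")
  expect_equal(single, archer_transmission(p, 1))
  # the product rule is an approximation: two published quarter-value-layer
  # half-stacks do not reproduce the exact transmission of the full stack
  gp <- get_archer_params("Tc-99m", "gypsum")
  two_halves <- composite_transmission(list(
    list(material = "gypsum", thickness_mm = 115),
    list(material = "gypsum", thickness_mm = 115)), "Tc-99m")
  exact <- archer_transmission(gp, 230)
  expect_equal(two_halves, 0.25, tolerance = 0.2)
  expect_false(isTRUE(all.equal(two_halves, exact, tolerance = 1e-6)))
})

test_that("scenario configs round-trip through YAML and JSON", {
  cfg <- list(nuclide = "Lu-177",
              workload = list(activity_mCi = 200, hours = 4,
                              sessions_per_week = 5, apply_decay = FALSE),
              distance_cm = 240, limit_uGy_per_week = 20,
              occupancy = "office", material = "lead")
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  jsn <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE), jsn)
  for (path in c(yml, jsn)) {
    sc <- read_scenario(path)
    expect_equal(sc$workload$mci_hours, 4000)
    expect_equal(sc$occupancy, 1)
    expect_equal(sc$distance_cm, 240)
    sol <- solve_barrier(sc)
    expect_signif3(sol$required_thickness_mm, 1.48)
  }
  expect_error(read_scenario("/nonexistent.yaml"), "not found")
})

test_that("component distances add up to the total separation", {
  sc <- shielding_scenario("Lu-177", workload("Lu-177", 4000), "lead",
                           source_to_barrier_cm = 198,
                           wall_thickness_cm = 11.4,
                           barrier_to_poc_cm = 30)
  expect_equal(sc$distance_cm, 239.4)
})
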
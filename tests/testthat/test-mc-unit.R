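# cross-section grids, emission sampling, single-photon transport and ROI
# scoring

test_that("embedded cross-section grids are well formed over 15-700 keV", {
  for (el in c("H", "O", "Ca", "Fe", "Pb")) {
    g <- element_xsec(el)
    expect_true(all(diff(g$energy_keV) > 0))
    expect_lte(min(g$energy_keV), 15)
    expect_gte(max(g$energy_keV), 700)
    expect_true(all(g$incoh_cm2_g > 0))
    expect_true(all(g$photo_cm2_g >= 0))
  }
  expect_error(element_xsec("Xx"), "no cross-section")
})

test_that("material attenuation follows the mixture rule and known physics", {
  # mixture rule: a 50/50 fictitious split reproduces the weighted sum
  e <- c(100, 140, 364, 511)
  mu_pb <- mass_attenuation("lead", e)
  expect_true(all(diff(mu_pb) < 0))            # decreasing between edges
  # lead K-edge: photoelectric jumps upward just above 88 keV
  below <- mass_attenuation("lead", 87.9, kind = "photo")
  above <- mass_attenuation("lead", 88.1, kind = "photo")
  expect_gt(above / below, 2)
  # soft tissue at 140 keV is dominated by Compton, near 0.15 cm^2/g
  mu_mus <- mass_attenuation("muscle", 140)
  expect_gt(mu_mus, 0.12)
  expect_lt(mu_mus, 0.18)
  # total = photo + incoherent
  expect_equal(mass_attenuation("glass", e),
               mass_attenuation("glass", e, "photo") +
               mass_attenuation("glass", e, "incoh"))
  expect_equal(mu_linear("lead", 140),
               11.35 * mass_attenuation("lead", 140))
})

test_that("emission sampling uses the embedded lines and the forward hemisphere", {
  set.seed(7)
  s <- sample_emission("Lu-177", 40000)
  expect_setequal(unique(s$energy_keV), c(113, 208))
  frac208 <- mean(s$energy_keV == 208)
  # yields 6% and 11% renormalized: P(208) = 11/17, binomial 4-sigma band
  expect_equal(frac208, 11 / 17, tolerance = 4 * sqrt(11/17 * 6/17 / 40000) / (11/17))
  expect_true(all(s$dz > 0))
  norms <- with(s, dx^2 + dy^2 + dz^2)
  expect_equal(norms, rep(1, nrow(s)), tolerance = 1e-12)
  tc <- sample_emission("Tc-99m", 100)
  expect_true(all(tc$energy_keV == 140))
})

# a one-material test world spanning a large box
test_world <- function(mu_photo, mu_incoh) {
  list(boxes = matrix(numeric(0), ncol = 7),
       world = c(-500, 500, -500, 500, -500, 500),
       world_mat = 1,
       materials = list(list(energy_keV = c(15, 700),
                             mu_photo = c(mu_photo, mu_photo),
                             mu_incoh = c(mu_incoh, mu_incoh))),
       material_names = "test", source = c(0, 0, 0), tissue_box = NULL)
}

test_that("transport in a vacuum-like medium deposits nothing", {
  w <- test_world(0, 0)
  dep <- transport_photon(200, c(0, 0, 0), c(0, 0, 1), w, seed = 1)
  expect_equal(nrow(dep), 0)
})

test_that("a photoelectric-only medium gives exactly one full-energy deposition", {
  w <- test_world(0.5, 0)
  for (seed in 1:20) {
    dep <- transport_photon(140, c(0, 0, 0), c(0, 0, 1), w, seed = seed)
    expect_equal(nrow(dep), 1)
    expect_equal(dep$edep_keV, 140)
    expect_equal(dep$x_cm, 0)
    expect_gt(dep$z_cm, 0)
  }
})

test_that("energy is conserved within each history", {
  cfg <- sim_config("I-131", "lead", 2, n_histories = 1, seed = 1)
  w <- nmshield:::mc_world(cfg)
  for (seed in 1:50) {
    dep <- transport_photon(364, c(0, 0, 0), c(0, 0, 1), w, seed = seed)
    if (nrow(dep)) expect_lte(sum(dep$edep_keV), 364 + 1e-9)
  }
})

test_that("free paths in lead reproduce the embedded attenuation coefficient", {
  # narrow-beam survival through t of lead estimates exp(-mu t); invert for mu
  t_mm <- 0.27
  cfg <- sim_config("Tc-99m", "lead", t_mm, n_histories = 2e5, seed = 31,
                    narrow_beam = TRUE)
  r <- simulate_transmission(cfg)
  mu_hat <- -log(r$transmission) / (t_mm / 10)    # 1/cm
  expect_equal(mu_hat, mu_linear("lead", 140), tolerance = 0.01)
})

test_that("ROI scoring matches the closed-form voxel dose", {
  expect_identical(score_roi_dose(data.frame()), 0)
  # one unit of energy at the centre of every ROI voxel in depth planes 2-3
  lat <- seq(-100 + 0.125, 100, by = 0.25)
  keep <- abs(lat) <= 7.6   # superset; filter by radius below
  grid <- expand.grid(x = lat[keep], y = lat[keep])
  grid <- grid[grid$x^2 + grid$y^2 <= 7.5^2, ]
  dep <- rbind(
    data.frame(x_cm = grid$x, y_cm = grid$y, z_cm = 175.75, edep_keV = 1),
    data.frame(x_cm = grid$x, y_cm = grid$y, z_cm = 176.25, edep_keV = 1))
  vox_mass_kg <- 1.05 * 0.5 * 0.25 * 0.25 / 1000
  expect_equal(score_roi_dose(dep, n_decays = 1),
               1 * 1.602176634e-16 / vox_mass_kg)
  # energy outside the ROI planes does not score
  outside <- data.frame(x_cm = 0, y_cm = 0, z_cm = 180, edep_keV = 100)
  expect_identical(score_roi_dose(outside), 0)
  far <- data.frame(x_cm = 50, y_cm = 0, z_cm = 176, edep_keV = 100)
  expect_identical(score_roi_dose(far), 0)
})

test_that("simulation configs validate their inputs", {
  expect_error(sim_config("Lu-177", "lead", 1, n_histories = 1e4),
               "seed")
  expect_error(sim_config("Lu-177", "lead", -1, seed = 1), "\\[0, 500\\]")
  expect_error(sim_config("Lu-177", "lead", 1, seed = 1,
                          ceiling_height_m = 3.05),
               "ceiling-floor")
  expect_error(sim_config("Lu-177", "lead", 1, seed = 1,
                          variant = "ceiling-floor", ceiling_height_m = 5),
               "3.05")
})

test_that("identical configs give bit-identical results", {
  cfg <- sim_config("Tc-99m", "lead", 0.5, n_histories = 5e4, seed = 77)
  a <- simulate_transmission(cfg)
  b <- simulate_transmission(cfg)
  expect_identical(a$transmission, b$transmission)
  expect_identical(a$dose_per_decay, b$dose_per_decay)
  # a different master seed gives a different estimate
  cfg2 <- sim_config("Tc-99m", "lead", 0.5, n_histories = 5e4, seed = 78)
  expect_false(identical(simulate_transmission(cfg2)$transmission,
                         a$transmission))
})

test_that("zero-thickness transmission is exactly 1", {
  cfg <- sim_config("Lu-177", "lead", 0, n_histories = 2e4, seed = 5)
  r <- simulate_transmission(cfg)
  expect_identical(r$transmission, 1)
  expect_identical(buildup_factor(r, mu_linear("lead", 208) / 10), 1)
})

test_that("buildup is rejected for narrow-beam results", {
  cfg <- sim_config("Tc-99m", "lead", 0.5, n_histories = 1e4, seed = 2,
                    narrow_beam = TRUE)
  r <- simulate_transmission(cfg)
  expect_error(buildup_factor(r, 2.57), "broad-beam")
})

test_that("run_curve returns a fit-ready monotone curve", {
  empty <- run_curve("Lu-177", "lead", numeric(0), seed = 1)
  expect_equal(nrow(empty), 0)
  cv <- run_curve("Lu-177", "lead", c(0.5, 1, 2, 4), n_histories = 1e6,
                  seed = 19)
  expect_s3_class(cv, "transmission_curve")
  expect_true(all(diff(cv$transmission) < 0))
  # fit-simulation closure: the fitted curve reproduces the simulated
  # transmissions within 3 combined standard deviations
  fit <- fit_archer(cv)
  pred <- archer_transmission(fit$params, cv$thickness_mm)
  expect_true(all(abs(pred - cv$transmission) <= 3 * pmax(cv$sd, 1e-6)))
})
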
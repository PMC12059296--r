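# transcription and lookup behaviour of the shipped physical data tables

test_that("nuclide records carry the published constants", {
  lu <- get_nuclide("Lu-177")
  expect_equal(lu$gamma_constant, 0.181)
  expect_equal(lu$f_factor, 0.957)
  expect_equal(lu$half_life_value, 6.65)
  expect_equal(lu$half_life_unit, "d")
  expect_equal(lu$photon_lines$energy_keV, c(113, 208))
  expect_equal(lu$photon_lines$yield, c(0.06, 0.11))

  tc <- get_nuclide("Tc-99m")
  expect_equal(tc$half_life_value, 6.02)
  expect_equal(tc$half_life_unit, "h")
  expect_equal(tc$photon_lines$energy_keV, 140)
  expect_equal(tc$photon_lines$yield, 0.8907)
  expect_equal(tc$gamma_constant, 0.795)
  expect_equal(tc$f_factor, 0.959)

  i131 <- get_nuclide("I-131")
  expect_equal(i131$gamma_constant, 2.2)
  expect_equal(i131$f_factor, 0.963)
  expect_equal(i131$photon_lines$energy_keV, c(364, 637))

  f18 <- get_nuclide("F-18")
  expect_equal(f18$gamma_constant, 5.7)
  expect_equal(f18$f_factor, 0.876)
  expect_equal(f18$photon_lines$yield, 1.94)  # 194%: ~2 annihilation photons
})

test_that("nuclide invariants hold for all shipped records", {
  names <- c("Tc-99m", "F-18", "I-131", "Lu-177")
  for (nm in names) {
    nuc <- get_nuclide(nm)
    expect_gt(nuc$gamma_constant, 0)
    expect_gt(nuc$f_factor, 0)
    expect_lte(nuc$f_factor, 1)
    expect_true(all(nuc$photon_lines$energy_keV >= 15))
    expect_true(all(nuc$photon_lines$yield > 1e-4))
  }
})

test_that("nuclide aliases resolve and unknown nuclides error informatively", {
  expect_equal(get_nuclide("tc99m")$name, "Tc-99m")
  expect_equal(get_nuclide("99mTc")$name, "Tc-99m")
  expect_equal(get_nuclide("177Lu")$name, "Lu-177")
  expect_error(get_nuclide("Xe-133"), "Tc-99m, F-18, I-131, Lu-177")
})

test_that("Archer parameter lookup returns printed values and rejects excluded pairs", {
  p <- get_archer_params("Lu-177", "lead")
  expect_equal(c(p$alpha, p$beta, p$gamma), c(0.3855, 1.071, 0.2822))
  p2 <- get_archer_params("Tc-99m", "glass")
  expect_equal(c(p2$alpha, p2$beta, p2$gamma), c(0.03419, -0.02009, 0.3076))
  expect_error(get_archer_params("F-18", "gypsum"), "negligible attenuation")
  expect_error(get_archer_params("I-131", "gypsum"), "negligible attenuation")
  expect_error(get_archer_params("F-18", "glass"), "available pairs")
})

test_that("every published Archer cell is transcribed exactly", {
  pub <- published_archer()
  for (i in seq_len(nrow(pub))) {
    p <- get_archer_params(pub$nuclide[i], pub$material[i])
    expect_equal(c(p$alpha, p$beta, p$gamma),
                 c(pub$alpha[i], pub$beta[i], pub$gamma[i]),
                 info = paste(pub$nuclide[i], pub$material[i]))
  }
  expect_equal(nrow(list_archer_pairs()), 21L)
})

test_that("TG-108 comparison rows are stored but separate", {
  tg <- get_archer_params("F-18", "lead", source = "TG-108")
  expect_equal(c(tg$alpha, tg$beta, tg$gamma), c(0.1543, -0.04406, 2.133))
  this <- get_archer_params("F-18", "lead")
  expect_false(isTRUE(all.equal(tg$alpha, this$alpha)))
  expect_equal(nrow(list_archer_pairs("TG-108")), 3L)
})

test_that("material records match the printed compositions and densities", {
  gy <- get_material("gypsum")
  expect_equal(gy$density, 2.33)
  expect_equal(gy$composition[["Ca"]], 0.23279)
  expect_equal(gy$composition[["H"]], 0.0234)
  expect_equal(get_material("LW concrete")$density, 1.6)
  expect_equal(get_material("NW concrete")$density, 2.3)
  expect_equal(get_material("air")$density, 0.001205)
  expect_equal(get_material("A514 steel")$density, 7.85)
  expect_equal(get_material("muscle")$density, 1.05)
  pb <- get_material("lead")
  expect_equal(pb$density, 11.35)
  expect_equal(pb$source, "added")   # not part of the published table
  expect_error(get_material("adamantium"), "unknown material")
})

test_that("all composition rows sum to 1 within 1e-3", {
  for (nm in c("air", "glass", "LW concrete", "NW concrete", "A514 steel",
               "gypsum", "muscle", "lead")) {
    mat <- get_material(nm)
    expect_equal(sum(mat$composition), 1, tolerance = 1e-3, info = nm)
    expect_gt(mat$density, 0)
  }
})

test_that("occupancy keyword matching follows the recommended table", {
  expect_equal(get_occupancy("office"), 1)
  expect_equal(get_occupancy("imaging rooms"), 1)
  expect_equal(get_occupancy("patient treatment rooms"), 0.5)
  expect_equal(get_occupancy("corridor"), 1 / 5)
  expect_equal(get_occupancy("corridor doors"), 1 / 8)
  expect_equal(get_occupancy("public toilets"), 1 / 20)
  expect_equal(get_occupancy("stairway"), 1 / 40)
  expect_error(get_occupancy("spaceship"), "valid areas")
  # all factors are from the recommended set
  tab <- nmshield:::occupancy_table()
  expect_true(all(tab$occupancy_factor %in% c(1, 1/2, 1/5, 1/8, 1/20, 1/40)))
})

test_that("dump_tables writes audit copies equal to the shipped tables", {
  dir <- withr::local_tempdir()
  paths <- dump_tables(dir)
  expect_true(all(file.exists(paths)))
  dumped <- read.csv(file.path(dir, "archer_params.csv"))
  expect_equal(nrow(dumped), 24L)  # 21 fitted + 3 TG-108 rows
})
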
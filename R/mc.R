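# Simplified analog Monte Carlo photon transport in the source-barrier-
# tissue slab geometry, for generating broad-beam transmission and buildup
# factors.
#
# Geometry (infinite-barrier variant, all coordinates in cm): an air-filled
# world 3 m long (z) by 2 m by 2 m; a barrier spanning the full cross
# section centred 1 m from the point source along +z; a 2 m x 2 m x 50 cm
# muscle block whose central plane is 1 m behind the barrier centre. The
# source emits into the +z hemisphere only. Doses are scored in voxels 5 mm
# deep (along z) by 2.5 mm square, averaged over the second and third depth
# planes of a 150 mm diameter region of interest - an estimate of the dose
# at 1 cm tissue depth (the deep-dose-equivalent surrogate).
#
# The ceiling-floor variant adds a light-weight-concrete floor and ceiling
# (7.5 cm thick) and shrinks the barrier to 2.14 m x 2.14 m so photons can
# scatter over it; the ROI can then sit on the front (vertical) face or the
# top face of the tissue block.

KEV_TO_J <- 1.602176634e-16

CEILING_HEIGHTS_M <- c(3.05, 3.66, 4.27, 4.88)

# deterministic per-run stream seeds derived from one master seed
derive_seed <- function(seed, k) {
  (seed * 2654435761 + k * 40503 + 1013904223) %% 2147483647
}

#' Describe a Monte Carlo transmission run
#'
#' @param nuclide Nuclide identifier; its embedded photon lines define the
#'   source spectrum.
#' @param material Barrier material identifier.
#' @param thickness_mm Barrier thickness, mm (0 = no barrier).
#' @param n_histories Number of source photons to simulate.
#' @param seed Integer master seed (mandatory; per-run streams are derived
#'   from it).
#' @param variant `"infinite-barrier"` (barrier spans the world cross
#'   section) or `"ceiling-floor"` (finite barrier plus concrete floor and
#'   ceiling).
#' @param ceiling_height_m Ceiling height above the floor, one of 3.05,
#'   3.66, 4.27 or 4.88 m; only with the ceiling-floor variant.
#' @param narrow_beam If `TRUE`, simulate the idealized narrow-beam
#'   geometry instead: a pencil beam through the barrier in vacuum, where
#'   transmission is the unscattered survival fraction `exp(-mu x)`.
#' @param roi For the ceiling-floor variant, `"front"` scores the usual
#'   ROI on the proximal face, `"top"` scores a 150 mm ROI on the top face
#'   of the tissue block (used when the barrier is nearly opaque and
#'   over-barrier scatter dominates).
#' @param lines Optional data frame `energy_keV`, `yield` overriding the
#'   nuclide's embedded emission lines.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(nuclide, material, thickness_mm,
                       n_histories = 2e6, seed,
                       variant = c("infinite-barrier", "ceiling-floor"),
                       ceiling_height_m = NULL, narrow_beam = FALSE,
                       roi = c("front", "top"), lines = NULL) {
  variant <- match.arg(variant)
  roi <- match.arg(roi)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  nm <- normalize_nuclide(nuclide)
  mat <- normalize_material(material)
  stopifnot(is.numeric(thickness_mm), length(thickness_mm) == 1L)
  if (thickness_mm < 0 || thickness_mm > 500) {
    stop("barrier thickness must be in [0, 500] mm", call. = FALSE)
  }
  if (n_histories < 1) stop("n_histories must be positive", call. = FALSE)
  if (variant == "ceiling-floor") {
    if (is.null(ceiling_height_m)) ceiling_height_m <- 3.05
    if (!any(abs(ceiling_height_m - CEILING_HEIGHTS_M) < 1e-9)) {
      stop("ceiling_height_m must be one of ",
           paste(CEILING_HEIGHTS_M, collapse = ", "), " m", call. = FALSE)
    }
  } else if (!is.null(ceiling_height_m)) {
    stop("ceiling_height_m applies only to the ceiling-floor variant",
         call. = FALSE)
  }
  if (is.null(lines)) {
    lines <- get_nuclide(nm)$photon_lines
  } else {
    stopifnot(is.data.frame(lines),
              all(c("energy_keV", "yield") %in% names(lines)),
              nrow(lines) >= 1, all(lines$yield > 0))
  }
  structure(list(nuclide = nm, material = mat, thickness_mm = thickness_mm,
                 n_histories = n_histories, seed = seed, variant = variant,
                 ceiling_height_m = ceiling_height_m,
                 narrow_beam = isTRUE(narrow_beam), roi = roi,
                 lines = lines),
            class = "sim_config")
}

# ---- world construction -------------------------------------------------

# materials are indexed into the world's material list by name
world_materials <- function(names) {
  lapply(names, function(nm) {
    if (nm == "vacuum") vacuum_mu_table() else material_mu_table(nm)
  })
}

# infinite-barrier world: slabs across the full 2 m x 2 m cross section
build_world_infinite <- function(barrier_material, thickness_mm,
                                 narrow_beam = FALSE) {
  t_cm <- thickness_mm / 10
  if (narrow_beam) {
    mats <- c("vacuum", barrier_material)
    boxes <- if (t_cm > 0) {
      matrix(c(-100, 100, -100, 100, 100 - t_cm / 2, 100 + t_cm / 2, 2),
             nrow = 1)
    } else {
      matrix(numeric(0), ncol = 7)
    }
    return(list(boxes = boxes, world = c(-100, 100, -100, 100, -50, 250),
                world_mat = 1, materials = world_materials(mats),
                material_names = mats, source = c(0, 0, 0),
                tissue_box = NULL))
  }
  mats <- c("air", barrier_material, "muscle")
  boxes <- rbind(
    if (t_cm > 0) c(-100, 100, -100, 100, 100 - t_cm / 2, 100 + t_cm / 2, 2),
    c(-100, 100, -100, 100, 175, 225, 3))
  list(boxes = boxes, world = c(-100, 100, -100, 100, -50, 250),
       world_mat = 1, materials = world_materials(mats),
       material_names = mats, source = c(0, 0, 0),
       tissue_box = c(-100, 100, -100, 100, 175, 225))
}

# ceiling-floor world: finite barrier, LW concrete floor and ceiling
build_world_ceiling <- function(barrier_material, thickness_mm,
                                ceiling_height_m) {
  t_cm <- thickness_mm / 10
  h_cm <- ceiling_height_m * 100
  mats <- c("air", barrier_material, "muscle", "LW concrete")
  # floor top at y = -100 (source 1 m above it); ceiling bottom at
  # y = -100 + h; barrier 2.14 m wide/tall resting on the floor
  boxes <- rbind(
    if (t_cm > 0) c(-107, 107, -100, 114, 100 - t_cm / 2, 100 + t_cm / 2, 2),
    c(-100, 100, -100, 100, 175, 225, 3),
    c(-150, 150, -107.5, -100, -50, 250, 4),
    c(-150, 150, -100 + h_cm, -92.5 + h_cm, -50, 250, 4))
  list(boxes = boxes,
       world = c(-150, 150, -110, -90 + h_cm, -50, 250),
       world_mat = 1, materials = world_materials(mats),
       material_names = mats, source = c(0, 0, 0),
       tissue_box = c(-100, 100, -100, 100, 175, 225))
}

mc_world <- function(config, with_barrier = TRUE) {
  t_mm <- if (with_barrier) config$thickness_mm else 0
  if (config$narrow_beam) {
    build_world_infinite(config$material, t_mm, narrow_beam = TRUE)
  } else if (config$variant == "infinite-barrier") {
    build_world_infinite(config$material, t_mm)
  } else {
    build_world_ceiling(config$material, t_mm, config$ceiling_height_m)
  }
}

roi_spec_for <- function(config, world) {
  if (is.null(world$tissue_box)) return(list(mode = 0L))
  if (config$variant == "ceiling-floor" && config$roi == "top") {
    # ROI circle on the top face, centred 10 cm + one radius behind the
    # front edge of the tissue block
    list(mode = 2L, box = world$tissue_box, plane_cm = 0.5, lat_cm = 0.25,
         radius_cm = 7.5, center = c(0, 175 + 10 + 7.5))
  } else {
    list(mode = 1L, box = world$tissue_box, plane_cm = 0.5, lat_cm = 0.25,
         radius_cm = 7.5, center = c(0, 0))
  }
}

# number of lateral voxels whose centre lies inside the ROI circle, and the
# voxel mass, for converting scored energy to mean voxel dose
roi_voxel_geometry <- function(roi_spec, density_g_cm3 = 1.05) {
  box <- roi_spec$box
  if (roi_spec$mode == 1L) {
    u1 <- seq(box[1] + roi_spec$lat_cm / 2, box[2], by = roi_spec$lat_cm)
    u2 <- seq(box[3] + roi_spec$lat_cm / 2, box[4], by = roi_spec$lat_cm)
    ctr <- roi_spec$center
  } else {
    u1 <- seq(box[1] + roi_spec$lat_cm / 2, box[2], by = roi_spec$lat_cm)
    u2 <- seq(box[5] + roi_spec$lat_cm / 2, box[6], by = roi_spec$lat_cm)
    ctr <- roi_spec$center
  }
  d2 <- outer((u1 - ctr[1])^2, (u2 - ctr[2])^2, "+")
  n_lat <- sum(d2 <= roi_spec$radius_cm^2)
  vox_mass_g <- density_g_cm3 * roi_spec$plane_cm * roi_spec$lat_cm^2
  list(n_voxels = 2L * n_lat,  # two depth planes
       voxel_mass_kg = vox_mass_g / 1000)
}

# ---- operations ---------------------------------------------------------

#' Sample source photon emissions for a nuclide
#'
#' Energies are drawn proportional to the embedded line yields; directions
#' are uniform over the hemisphere oriented toward the barrier (+z). Uses
#' R's RNG (seed with [set.seed()] for reproducibility). This is the
#' reference sampler that the compiled transport kernel replicates.
#'
#' @param nuclide Nuclide identifier.
#' @param n Number of samples.
#' @return Data frame with `energy_keV`, `dx`, `dy`, `dz` (unit vectors,
#'   `dz > 0`).
#' @export
sample_emission <- function(nuclide, n = 1) {
  lines <- get_nuclide(nuclide)$photon_lines
  prob <- lines$yield / sum(lines$yield)
  e <- lines$energy_keV[sample.int(nrow(lines), n, replace = TRUE, prob = prob)]
  cz <- runif(n)                      # cos(theta) uniform on (0,1): 2pi emission
  phi <- 2 * pi * runif(n)
  s <- sqrt(pmax(0, 1 - cz^2))
  data.frame(energy_keV = e, dx = s * cos(phi), dy = s * sin(phi), dz = cz)
}

#' Transport a single photon and record its energy depositions
#'
#' Runs the analog transport kernel for one history in a given world and
#' returns every local energy deposition (photoelectric absorption, Compton
#' electron energy, sub-cutoff residuals). Intended for inspection and
#' testing; bulk runs use [simulate_transmission()].
#'
#' @param energy_keV Initial photon energy (>= the 15 keV cutoff).
#' @param origin,direction Numeric length-3 position (cm) and unit
#'   direction.
#' @param world A world description as built by the simulator (see
#'   [sim_config()]); tests may construct custom worlds.
#' @param seed Integer seed.
#' @return Data frame with `x_cm`, `y_cm`, `z_cm`, `edep_keV`, one row per
#'   deposition (possibly zero rows).
#' @export
transport_photon <- function(energy_keV, origin, direction, world, seed) {
  stopifnot(energy_keV >= 15, length(origin) == 3, length(direction) == 3)
  direction <- direction / sqrt(sum(direction^2))
  res <- .mc_run(world_spec = world, roi_spec = list(mode = 0L),
                 lines = matrix(c(energy_keV, 1), nrow = 1),
                 source = as.numeric(origin), emission = "pencil",
                 fixed_dir = as.numeric(direction),
                 n_histories = 1, seed = seed, cutoff = 15,
                 narrow_beam = FALSE, record = TRUE)
  as.data.frame(res$depositions)
}

#' Mean voxel dose in the scoring region of interest
#'
#' Voxelizes depositions inside the tissue block (5 mm depth planes, 2.5 mm
#' lateral pitch), keeps the second and third depth planes of voxels whose
#' centres fall inside the 150 mm diameter ROI circle, and returns the mean
#' voxel dose divided by the number of simulated decays.
#'
#' @param depositions Data frame with `x_cm`, `y_cm`, `z_cm`, `edep_keV`.
#' @param n_decays Number of simulated decays the depositions came from.
#' @param tissue_box Tissue block bounds
#'   `c(xmin, xmax, ymin, ymax, zmin, zmax)` in cm; default the standard
#'   geometry's block.
#' @param density_g_cm3 Tissue density.
#' @return Dose in Gy per decay (0 for an empty deposition set).
#' @export
score_roi_dose <- function(depositions, n_decays = 1,
                           tissue_box = c(-100, 100, -100, 100, 175, 225),
                           density_g_cm3 = 1.05) {
  spec <- list(mode = 1L, box = tissue_box, plane_cm = 0.5, lat_cm = 0.25,
               radius_cm = 7.5, center = c(0, 0))
  geom <- roi_voxel_geometry(spec, density_g_cm3)
  if (is.null(depositions) || nrow(depositions) == 0) return(0)
  d <- depositions
  inside <- d$x_cm >= tissue_box[1] & d$x_cm < tissue_box[2] &
    d$y_cm >= tissue_box[3] & d$y_cm < tissue_box[4] &
    d$z_cm >= tissue_box[5] & d$z_cm < tissue_box[6]
  d <- d[inside, , drop = FALSE]
  if (nrow(d) == 0) return(0)
  plane <- floor((d$z_cm - tissue_box[5]) / spec$plane_cm)  # 0-based
  vx <- tissue_box[1] + (floor((d$x_cm - tissue_box[1]) / spec$lat_cm) + 0.5) * spec$lat_cm
  vy <- tissue_box[3] + (floor((d$y_cm - tissue_box[3]) / spec$lat_cm) + 0.5) * spec$lat_cm
  in_roi <- plane %in% c(1, 2) & (vx^2 + vy^2 <= spec$radius_cm^2)
  e_kev <- sum(d$edep_keV[in_roi])
  e_kev * KEV_TO_J / geom$voxel_mass_kg / geom$n_voxels / n_decays
}

run_kernel <- function(config, world, seed) {
  roi <- roi_spec_for(config, world)
  lines <- as.matrix(config$lines[, c("energy_keV", "yield")])
  res <- .mc_run(world_spec = world, roi_spec = roi, lines = lines,
                 source = world$source,
                 emission = if (config$narrow_beam) "pencil" else "hemisphere",
                 fixed_dir = c(0, 0, 1),
                 n_histories = config$n_histories, seed = seed,
                 cutoff = 15, narrow_beam = config$narrow_beam,
                 record = FALSE)
  res$roi <- roi
  res
}

# mean per-history ROI energy -> Gy per decay, with relative sd
kernel_dose <- function(res, config) {
  weight <- sum(config$lines$yield)     # photons per decay
  n <- res$n
  mean_e <- res$sum_e_keV / n
  var_e <- max(res$sum_e2_keV2 / n - mean_e^2, 0)
  sd_mean <- sqrt(var_e / n)
  geom <- roi_voxel_geometry(res$roi)
  scale <- weight * KEV_TO_J / geom$voxel_mass_kg / geom$n_voxels
  list(dose = mean_e * scale,
       rel_sd = if (mean_e > 0) sd_mean / mean_e else NA_real_)
}

#' Run a broad-beam (or narrow-beam) transmission simulation
#'
#' Broad beam: two paired runs with seeds derived from the master seed -
#' one with the barrier, one without - and transmission is the ratio of the
#' scored ROI doses. A zero-thickness barrier is identical to no barrier,
#' so its transmission is exactly 1 (no second run). Narrow beam: a pencil
#' beam through the barrier in vacuum; transmission is the unscattered
#' survival fraction, the Monte Carlo estimate of `exp(-mu x)`.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_result` with fields `dose_per_decay`
#'   (Gy/decay in the ROI), `relative_sd`, `air_dose_per_decay`,
#'   `air_relative_sd`, `transmission`, `transmission_sd`, `narrow_beam`,
#'   `n_histories`, `config`.
#' @export
simulate_transmission <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("'config' must be a sim_config", call. = FALSE)
  }
  if (config$narrow_beam) {
    world <- mc_world(config, with_barrier = TRUE)
    res <- run_kernel(config, world, derive_seed(config$seed, 1))
    tr <- res$n_transmitted / res$n
    tr_sd <- sqrt(max(tr * (1 - tr), 1e-300) / res$n)
    return(structure(list(
      dose_per_decay = NA_real_, relative_sd = NA_real_,
      air_dose_per_decay = NA_real_, air_relative_sd = NA_real_,
      transmission = tr, transmission_sd = tr_sd,
      narrow_beam = TRUE, n_histories = res$n, config = config),
      class = "sim_result"))
  }
  air <- air_reference_run(config)
  if (config$thickness_mm == 0) {
    return(structure(list(
      dose_per_decay = air$dose, relative_sd = air$rel_sd,
      air_dose_per_decay = air$dose, air_relative_sd = air$rel_sd,
      transmission = 1, transmission_sd = 0,
      narrow_beam = FALSE, n_histories = config$n_histories,
      config = config), class = "sim_result"))
  }
  world <- mc_world(config, with_barrier = TRUE)
  res <- run_kernel(config, world, derive_seed(config$seed, 1))
  bar <- kernel_dose(res, config)
  if (bar$dose == 0) {
    tr <- 0
    tr_sd <- NA_real_
  } else {
    tr <- bar$dose / air$dose
    tr_sd <- tr * sqrt(bar$rel_sd^2 + air$rel_sd^2)
  }
  structure(list(
    dose_per_decay = bar$dose, relative_sd = bar$rel_sd,
    air_dose_per_decay = air$dose, air_relative_sd = air$rel_sd,
    transmission = tr, transmission_sd = tr_sd,
    narrow_beam = FALSE, n_histories = config$n_histories,
    config = config), class = "sim_result")
}

# the paired no-barrier run (seed stream 2)
air_reference_run <- function(config) {
  world <- mc_world(config, with_barrier = FALSE)
  res <- run_kernel(config, world, derive_seed(config$seed, 2))
  out <- kernel_dose(res, config)
  if (out$dose == 0) {
    stop("no energy scored in the ROI of the no-barrier run; ",
         "increase n_histories", call. = FALSE)
  }
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result %s / %s %g mm, %s, %g histories>\n",
              x$config$nuclide, x$config$material, x$config$thickness_mm,
              if (x$narrow_beam) "narrow beam" else x$config$variant,
              x$n_histories))
  if (!x$narrow_beam) {
    cat(sprintf("  dose: %.4g Gy/decay (rel sd %.2g), air: %.4g Gy/decay\n",
                x$dose_per_decay, x$relative_sd, x$air_dose_per_decay))
  }
  cat(sprintf("  transmission: %.4g +- %.2g\n", x$transmission,
              x$transmission_sd))
  invisible(x)
}

#' Buildup factor implied by a broad-beam simulation
#'
#' `B = T_broad / exp(-mu x)`: the ratio of the simulated broad-beam
#' transmission to the ideal narrow-beam exponential at the same thickness.
#' At zero thickness B is exactly 1 by construction.
#'
#' @param result A broad-beam [simulate_transmission()] result.
#' @param mu_per_mm Linear attenuation coefficient, 1/mm (e.g.
#'   `mu_linear("lead", 140) / 10`).
#' @param thickness_mm Barrier thickness, mm (defaults to the result's).
#' @return Buildup factor (dimensionless, >= 1 within statistics).
#' @export
buildup_factor <- function(result, mu_per_mm,
                           thickness_mm = result$config$thickness_mm) {
  if (!inherits(result, "sim_result")) {
    stop("'result' must be a sim_result", call. = FALSE)
  }
  if (result$narrow_beam) {
    stop("buildup is defined for broad-beam results only", call. = FALSE)
  }
  result$transmission / exp(-mu_per_mm * thickness_mm)
}

#' Score the ROI dose for a configuration without a reference run
#'
#' Runs the barrier geometry only and returns the scored ROI dose. Useful
#' for scatter studies (e.g. the over-barrier ceiling-scatter dose behind
#' an effectively opaque barrier) where no transmission ratio is needed.
#'
#' @param config A broad-beam [sim_config()].
#' @return List with `dose_per_decay` (Gy/decay) and `relative_sd`.
#' @export
simulate_dose <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("'config' must be a sim_config", call. = FALSE)
  }
  if (config$narrow_beam) {
    stop("dose scoring applies to broad-beam configurations", call. = FALSE)
  }
  world <- mc_world(config, with_barrier = TRUE)
  res <- run_kernel(config, world, derive_seed(config$seed, 1))
  out <- kernel_dose(res, config)
  list(dose_per_decay = out$dose, relative_sd = out$rel_sd)
}

#' Simulate the buildup factor over several thicknesses
#'
#' Runs one broad-beam barrier simulation per thickness and derives
#' `B = T / exp(-mu x)`. All barrier runs use the *same* derived RNG
#' stream and share one no-barrier reference run (common random numbers):
#' the unscattered component is then sampled identically across
#' thicknesses, which makes differences and trends of B across thickness
#' far more precise than the individual B values. Use this, rather than
#' independent [simulate_transmission()] calls, when the question is how
#' buildup changes with thickness.
#'
#' @param nuclide,material Identifiers.
#' @param thicknesses_mm Barrier thicknesses, mm (> 0).
#' @param n_histories Histories per run.
#' @param seed Master seed.
#' @param mu_per_mm Linear attenuation coefficient used in the narrow-beam
#'   reference, 1/mm; defaults to the embedded coefficient at the
#'   nuclide's highest-yield line.
#' @return Data frame with columns `thickness_mm`, `transmission`,
#'   `transmission_sd`, `buildup`, `buildup_sd`.
#' @export
buildup_curve <- function(nuclide, material, thicknesses_mm,
                          n_histories = 2e6, seed, mu_per_mm = NULL) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(length(thicknesses_mm) >= 1, all(thicknesses_mm > 0))
  base <- sim_config(nuclide, material, thicknesses_mm[1],
                     n_histories = n_histories, seed = seed)
  if (is.null(mu_per_mm)) {
    lines <- base$lines
    e_dom <- lines$energy_keV[which.max(lines$yield)]
    mu_per_mm <- mu_linear(base$material, e_dom) / 10
  }
  air <- air_reference_run(base)
  out <- data.frame(thickness_mm = thicknesses_mm, transmission = NA_real_,
                    transmission_sd = NA_real_, buildup = NA_real_,
                    buildup_sd = NA_real_)
  for (i in seq_along(thicknesses_mm)) {
    cfg <- base
    cfg$thickness_mm <- thicknesses_mm[i]
    world <- mc_world(cfg, with_barrier = TRUE)
    res <- run_kernel(cfg, world, derive_seed(seed, 1))  # shared stream
    bar <- kernel_dose(res, cfg)
    tr <- bar$dose / air$dose
    tr_sd <- if (bar$dose > 0) tr * sqrt(bar$rel_sd^2 + air$rel_sd^2) else NA_real_
    narrow <- exp(-mu_per_mm * thicknesses_mm[i])
    out$transmission[i] <- tr
    out$transmission_sd[i] <- tr_sd
    out$buildup[i] <- tr / narrow
    out$buildup_sd[i] <- tr_sd / narrow
  }
  out
}

#' Simulate a broad-beam transmission curve over several thicknesses
#'
#' One barrier run per thickness (seed streams derived per thickness); the
#' no-barrier reference run is shared across thicknesses. Transmission
#' estimates above 1 are capped at 1 and zero-dose points are dropped with
#' a warning, so the result is a valid [transmission_curve()] ready for
#' [fit_archer()].
#'
#' @param nuclide,material Identifiers.
#' @param thicknesses_mm Strictly increasing thicknesses, mm.
#' @param n_histories Histories per run.
#' @param seed Master seed.
#' @param variant,ceiling_height_m Passed to [sim_config()].
#' @return A [transmission_curve()] with an `sd` column.
#' @export
run_curve <- function(nuclide, material, thicknesses_mm, n_histories = 2e6,
                      seed, variant = "infinite-barrier",
                      ceiling_height_m = NULL) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (length(thicknesses_mm) == 0) {
    return(transmission_curve(numeric(0), numeric(0),
                              nuclide = normalize_nuclide(nuclide),
                              material = normalize_material(material)))
  }
  base <- sim_config(nuclide, material, thicknesses_mm[1],
                     n_histories = n_histories, seed = seed,
                     variant = variant, ceiling_height_m = ceiling_height_m)
  air <- air_reference_run(base)
  tr <- sd <- numeric(length(thicknesses_mm))
  for (i in seq_along(thicknesses_mm)) {
    cfg <- base
    cfg$thickness_mm <- thicknesses_mm[i]
    if (thicknesses_mm[i] == 0) {
      tr[i] <- 1; sd[i] <- 0
      next
    }
    world <- mc_world(cfg, with_barrier = TRUE)
    res <- run_kernel(cfg, world, derive_seed(seed, 10 + i))
    bar <- kernel_dose(res, cfg)
    tr[i] <- bar$dose / air$dose
    sd[i] <- if (bar$dose > 0) tr[i] * sqrt(bar$rel_sd^2 + air$rel_sd^2) else NA_real_
  }
  keep <- tr > 0
  if (any(!keep)) {
    warning(sum(!keep), " thickness(es) scored zero dose and were dropped; ",
            "increase n_histories", call. = FALSE)
  }
  transmission_curve(thicknesses_mm[keep], pmin(tr[keep], 1), sd = sd[keep],
                     nuclide = base$nuclide, material = base$material)
}
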
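# The shielding-design chain: weekly workload -> unshielded dose at the
# point of concern -> required transmission under a dose limit and occupancy
# -> required barrier thickness via the inverse Archer equation.

MBQ_PER_MCI <- 37  # exact conversion used throughout

#' Construct a weekly workload
#'
#' The workload W is the weekly activity-time product (mCi h / week)
#' characterizing how much activity is present near the barrier and for how
#' long.
#'
#' @param nuclide Nuclide identifier.
#' @param mci_hours Weekly activity-time product, mCi h / week, `>= 0`.
#' @param description Free-text provenance, e.g. "5 patients x 200 mCi x 4 h".
#' @param decay_corrected Flag recording whether physical decay during each
#'   session was accounted for.
#' @return Object of class `workload`.
#' @export
workload <- function(nuclide, mci_hours, description = "",
                     decay_corrected = FALSE) {
  nm <- normalize_nuclide(nuclide)
  stopifnot(is.numeric(mci_hours), length(mci_hours) == 1L)
  if (!is.finite(mci_hours) || mci_hours < 0) {
    stop("workload must be >= 0 mCi h/week", call. = FALSE)
  }
  structure(list(nuclide = nm, mci_hours = mci_hours,
                 description = description,
                 decay_corrected = isTRUE(decay_corrected)),
            class = "workload")
}

#' @export
print.workload <- function(x, ...) {
  cat(sprintf("<workload %s>  %g mCi h/week%s%s\n", x$nuclide, x$mci_hours,
              if (x$decay_corrected) " (decay-corrected)" else "",
              if (nzchar(x$description)) paste0("  [", x$description, "]") else ""))
  invisible(x)
}

#' Weekly workload from a session pattern, optionally decay-corrected
#'
#' With decay off (the default, matching the usual conservative design
#' convention) the workload is `activity * hours * sessions`. With decay on,
#' each session's activity-time integral is reduced by the session-averaged
#' decay factor `(1 - exp(-lambda*t)) / (lambda*t)` with
#' `lambda = ln(2) / half-life`.
#'
#' @param activity_mCi Administered or present activity per session, mCi.
#'   Alternatively give `activity_GBq` (converted at exactly 37 MBq/mCi).
#' @param hours_per_session Residence time per session, hours.
#' @param sessions_per_week Number of sessions per week.
#' @param nuclide Nuclide identifier (sets the half-life for decay).
#' @param apply_decay Apply the session-averaged decay factor?
#' @param activity_GBq Optional activity in GBq instead of `activity_mCi`.
#' @return A [workload()] object.
#' @examples
#' decay_corrected_workload(200, 4, 5, "Lu-177")            # 4000 mCi h/wk
#' decay_corrected_workload(200, 4, 5, "Lu-177", TRUE)      # ~3965 mCi h/wk
#' @export
decay_corrected_workload <- function(activity_mCi = NULL, hours_per_session,
                                     sessions_per_week, nuclide,
                                     apply_decay = FALSE,
                                     activity_GBq = NULL) {
  if (is.null(activity_mCi)) {
    if (is.null(activity_GBq)) stop("give activity_mCi or activity_GBq",
                                    call. = FALSE)
    activity_mCi <- activity_GBq * 1000 / MBQ_PER_MCI
  }
  stopifnot(activity_mCi >= 0, hours_per_session >= 0, sessions_per_week >= 0)
  nuc <- get_nuclide(nuclide)
  w <- activity_mCi * hours_per_session * sessions_per_week
  factor <- 1
  if (isTRUE(apply_decay) && hours_per_session > 0) {
    lam <- log(2) / nuc$half_life_hours
    lt <- lam * hours_per_session
    factor <- (1 - exp(-lt)) / lt
  }
  workload(nuc$name, w * factor,
           description = sprintf("%g sessions/week x %g mCi x %g h%s",
                                 sessions_per_week, activity_mCi,
                                 hours_per_session,
                                 if (isTRUE(apply_decay)) " (decay on)" else ""),
           decay_corrected = isTRUE(apply_decay))
}

#' Unshielded weekly dose at a point of concern
#'
#' `D = W * Gamma * f / d^2`, with the exposure-rate constant Gamma in
#' R cm^2/(mCi h) at 1 cm, the f-factor converted to Gy/R, and the
#' source-to-point distance d in cm. The result is in micrograys per week
#' (numerically equal to uSv/week for these photon emitters, as an
#' ambient/deep-dose surrogate).
#'
#' @param workload A [workload()] object.
#' @param distance_cm Straight-line distance from source to the point of
#'   concern, cm, `> 0`.
#' @return Unshielded weekly dose, uGy/week.
#' @examples
#' w <- workload("Lu-177", 4000)
#' unshielded_weekly_dose(w, 240)  # 120.3 uGy/week
#' @export
unshielded_weekly_dose <- function(workload, distance_cm) {
  if (!inherits(workload, "workload")) {
    stop("'workload' must be a workload object", call. = FALSE)
  }
  stopifnot(is.numeric(distance_cm), length(distance_cm) == 1L)
  if (!is.finite(distance_cm) || distance_cm <= 0) {
    stop("distance must be > 0 cm", call. = FALSE)
  }
  nuc <- get_nuclide(workload$nuclide)
  f_gy_per_r <- nuc$f_factor / 100          # cGy/R -> Gy/R
  d_gy <- workload$mci_hours * nuc$gamma_constant * f_gy_per_r / distance_cm^2
  d_gy * 1e6                                # Gy -> uGy
}

#' Transmission required to meet a weekly dose limit
#'
#' `T = limit / (occupancy * unshielded)`, capped at 1 (no shielding
#' needed when the unshielded occupancy-weighted dose is already below the
#' limit).
#'
#' @param unshielded_uGy Unshielded weekly dose at the point of concern,
#'   uGy/week, `> 0`.
#' @param limit_uGy Weekly design dose limit, uGy/week, `> 0`
#'   (e.g. 20 for the US public limit of 1 mSv/year).
#' @param occupancy Occupancy factor in (0, 1].
#' @return Required transmission fraction in (0, 1].
#' @examples
#' required_transmission(120.3, 20)  # 0.166
#' @export
required_transmission <- function(unshielded_uGy, limit_uGy = 20,
                                  occupancy = 1) {
  stopifnot(is.numeric(unshielded_uGy), is.numeric(limit_uGy),
            is.numeric(occupancy))
  if (unshielded_uGy <= 0) stop("unshielded dose must be > 0", call. = FALSE)
  if (limit_uGy <= 0) stop("dose limit must be > 0", call. = FALSE)
  if (occupancy <= 0 || occupancy > 1) {
    stop("occupancy must be in (0, 1]", call. = FALSE)
  }
  min(1, limit_uGy / (occupancy * unshielded_uGy))
}

#' Describe a shielding scenario
#'
#' Bundles everything the barrier solver needs. Distance may be given
#' directly (`distance_cm`) or as components
#' `source_to_barrier_cm + wall_thickness_cm + barrier_to_poc_cm`.
#'
#' @param nuclide Nuclide identifier.
#' @param workload A [workload()] object, or a plain number of mCi h/week.
#' @param material Barrier material identifier.
#' @param distance_cm Total source-to-point-of-concern distance, cm.
#' @param source_to_barrier_cm,wall_thickness_cm,barrier_to_poc_cm
#'   Alternative distance components, cm.
#' @param limit_uGy_per_week Weekly design dose limit, uGy/week.
#' @param occupancy Occupancy factor in (0, 1], or an area key resolved via
#'   [get_occupancy()].
#' @return Object of class `shielding_scenario`.
#' @export
shielding_scenario <- function(nuclide, workload, material,
                               distance_cm = NULL,
                               source_to_barrier_cm = NULL,
                               wall_thickness_cm = 0,
                               barrier_to_poc_cm = NULL,
                               limit_uGy_per_week = 20,
                               occupancy = 1) {
  nm <- normalize_nuclide(nuclide)
  if (is.numeric(workload)) workload <- workload(nm, workload)
  if (!inherits(workload, "workload")) {
    stop("'workload' must be a workload object or a number", call. = FALSE)
  }
  if (workload$nuclide != nm) {
    stop("workload nuclide (", workload$nuclide,
         ") does not match scenario nuclide (", nm, ")", call. = FALSE)
  }
  if (is.null(distance_cm)) {
    if (is.null(source_to_barrier_cm) || is.null(barrier_to_poc_cm)) {
      stop("give distance_cm, or source_to_barrier_cm + barrier_to_poc_cm",
           call. = FALSE)
    }
    distance_cm <- source_to_barrier_cm + wall_thickness_cm + barrier_to_poc_cm
  }
  if (!is.numeric(distance_cm) || distance_cm <= 0) {
    stop("distance must be > 0 cm", call. = FALSE)
  }
  if (is.character(occupancy)) occupancy <- get_occupancy(occupancy)
  if (occupancy <= 0 || occupancy > 1) {
    stop("occupancy must be in (0, 1]", call. = FALSE)
  }
  mat <- normalize_material(material)
  structure(list(nuclide = nm, workload = workload, material = mat,
                 distance_cm = distance_cm,
                 limit_uGy_per_week = limit_uGy_per_week,
                 occupancy = occupancy),
            class = "shielding_scenario")
}

#' Solve a shielding scenario for the required barrier thickness
#'
#' Runs the full design chain: unshielded weekly dose at the point of
#' concern, transmission required to meet the occupancy-weighted dose
#' limit, and barrier thickness from the inverse Archer equation. A
#' warning is attached (and signalled) when the required transmission falls
#' below 0.01: at such transmissions scatter from the ceiling and floor
#' dominates the dose behind the barrier and thickening the barrier alone
#' is ineffective.
#'
#' @param scenario A [shielding_scenario()] object.
#' @return Object of class `barrier_solution` with fields
#'   `unshielded_weekly_dose` (uGy/week), `required_transmission`,
#'   `material`, `required_thickness_mm`, `decay_correction_applied`,
#'   `warnings`, and a `log` list of all intermediate quantities.
#' @examples
#' sc <- shielding_scenario("Lu-177", workload("Lu-177", 4000), "lead",
#'                          distance_cm = 240)
#' solve_barrier(sc)
#' @export
solve_barrier <- function(scenario) {
  if (!inherits(scenario, "shielding_scenario")) {
    stop("'scenario' must be a shielding_scenario object", call. = FALSE)
  }
  nuc <- get_nuclide(scenario$nuclide)
  d_ugys <- unshielded_weekly_dose(scenario$workload, scenario$distance_cm)
  t_req <- required_transmission(d_ugys, scenario$limit_uGy_per_week,
                                 scenario$occupancy)
  warnings <- character(0)
  if (t_req >= 1) {
    x_mm <- 0
  } else {
    params <- get_archer_params(scenario$nuclide, scenario$material)
    x_mm <- archer_thickness(params, t_req)
  }
  if (t_req < 0.01) {
    warnings <- c(warnings, paste0(
      "required transmission ", signif(t_req, 3), " is below 0.01: scatter ",
      "from the ceiling and floor severely limits the ability to shield for ",
      "transmission below 1%; a single thicker barrier may be inadequate"))
  }
  if (scenario$workload$decay_corrected) {
    warnings <- c(warnings, "workload includes a session-averaged decay correction")
  }
  for (w in warnings) warning(w, call. = FALSE)
  structure(list(
    nuclide = scenario$nuclide,
    material = scenario$material,
    unshielded_weekly_dose = d_ugys,
    required_transmission = t_req,
    required_thickness_mm = x_mm,
    decay_correction_applied = scenario$workload$decay_corrected,
    warnings = warnings,
    log = list(
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      tool_version = as.character(packageVersion("nmshield")),
      nuclide = scenario$nuclide,
      workload_mCi_h_per_week = scenario$workload$mci_hours,
      workload_description = scenario$workload$description,
      gamma_constant_R_cm2_per_mCi_h = nuc$gamma_constant,
      f_factor_cGy_per_R = nuc$f_factor,
      distance_cm = scenario$distance_cm,
      unshielded_weekly_dose_uGy = d_ugys,
      occupancy = scenario$occupancy,
      limit_uGy_per_week = scenario$limit_uGy_per_week,
      required_transmission = t_req,
      material = scenario$material,
      required_thickness_mm = x_mm
    )
  ), class = "barrier_solution")
}

#' @export
print.barrier_solution <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}

#' Transmission of a stack of barrier layers (product approximation)
#'
#' Multiplies per-layer Archer transmissions. This ignores the change of the
#' photon spectrum between layers (spectral hardening and inter-layer
#' buildup), so it is an approximation: a material's published parameters
#' describe a single barrier of that material, and the product of two
#' half-thickness transmissions is not exactly the transmission of the
#' doubled thickness.
#'
#' @param layers List of `list(material=, thickness_mm=)` pairs (or a
#'   2-column data frame).
#' @param nuclide Nuclide identifier.
#' @return Transmission fraction; 1 for an empty stack.
#' @export
composite_transmission <- function(layers, nuclide) {
  nm <- normalize_nuclide(nuclide)
  if (is.data.frame(layers)) {
    layers <- lapply(seq_len(nrow(layers)), function(i)
      list(material = layers$material[i], thickness_mm = layers$thickness_mm[i]))
  }
  tr <- 1
  for (ly in layers) {
    p <- get_archer_params(nm, ly$material)
    tr <- tr * archer_transmission(p, ly$thickness_mm)
  }
  tr
}

#' Read a shielding scenario from a YAML or JSON config file
#'
#' Recognized keys: `nuclide`, `material`, `limit_uGy_per_week`, `occupancy`
#' (a number or an area key), `distance_cm` or `source_to_barrier_cm` +
#' `wall_thickness_cm` + `barrier_to_poc_cm`, and either `workload_mCi_h`
#' or a `workload` block with `activity_mCi` (or `activity_GBq`), `hours`,
#' `sessions_per_week` and optional `apply_decay`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file (YAML is a superset of
#'   JSON, so both parse the same way).
#' @return A [shielding_scenario()] object.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- function(key) {
    if (is.null(cfg[[key]])) stop("config is missing key '", key, "'",
                                  call. = FALSE)
    cfg[[key]]
  }
  nuclide <- need("nuclide")
  wl <- if (!is.null(cfg$workload_mCi_h)) {
    workload(nuclide, cfg$workload_mCi_h)
  } else if (!is.null(cfg$workload)) {
    wb <- cfg$workload
    decay_corrected_workload(activity_mCi = wb$activity_mCi,
                             hours_per_session = wb$hours,
                             sessions_per_week = wb$sessions_per_week,
                             nuclide = nuclide,
                             apply_decay = isTRUE(wb$apply_decay),
                             activity_GBq = wb$activity_GBq)
  } else {
    stop("config needs 'workload_mCi_h' or a 'workload' block", call. = FALSE)
  }
  shielding_scenario(
    nuclide = nuclide, workload = wl, material = need("material"),
    distance_cm = cfg$distance_cm,
    source_to_barrier_cm = cfg$source_to_barrier_cm,
    wall_thickness_cm = if (is.null(cfg$wall_thickness_cm)) 0 else cfg$wall_thickness_cm,
    barrier_to_poc_cm = cfg$barrier_to_poc_cm,
    limit_uGy_per_week = if (is.null(cfg$limit_uGy_per_week)) 20 else cfg$limit_uGy_per_week,
    occupancy = if (is.null(cfg$occupancy)) 1 else cfg$occupancy)
}
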
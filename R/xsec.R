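# Embedded photon cross-section grids and the mixture rule.
#
# The shipped per-element grids (15-700 keV) carry photoelectric and
# incoherent (Compton) mass attenuation coefficients; coherent scattering
# is omitted. A material's mass attenuation coefficient is the
# mass-fraction-weighted sum of its elements' coefficients, and the linear
# coefficient is that times the density.

xsec_table <- function() {
  cached("xsec", function() {
    read.csv(nmshield_extdata("xsec", "elements.csv"), comment.char = "#")
  })
}

#' Photon cross-section grid for one element
#'
#' @param element Element symbol, e.g. `"Pb"`.
#' @return Data frame with `energy_keV`, `photo_cm2_g`, `incoh_cm2_g`;
#'   energies strictly increasing over 15-700 keV.
#' @export
element_xsec <- function(element) {
  tab <- xsec_table()
  hit <- tab[tab$element == element, ]
  if (nrow(hit) == 0L) {
    stop("no cross-section grid for element '", element, "'", call. = FALSE)
  }
  hit[order(hit$energy_keV),
      c("energy_keV", "photo_cm2_g", "incoh_cm2_g")]
}

# log-log interpolation of a positive tabulated function; zero-valued
# stretches (e.g. hydrogen photoelectric) interpolate through a floor
loglog_interp <- function(e_tab, y_tab, e) {
  ly <- log(pmax(y_tab, 1e-300))
  out <- approx(log(e_tab), ly, xout = log(e), rule = 2)$y
  y <- exp(out)
  y[y < 1e-290] <- 0
  y
}

#' Mass attenuation coefficient of a material (mixture rule)
#'
#' @param material Material identifier or [get_material()] object.
#' @param energy_keV Photon energies, keV (15-700 keV grid coverage).
#' @param kind `"total"` (photoelectric + incoherent), `"photo"` or
#'   `"incoh"`.
#' @return Mass attenuation coefficient(s), cm^2/g.
#' @export
mass_attenuation <- function(material, energy_keV,
                             kind = c("total", "photo", "incoh")) {
  kind <- match.arg(kind)
  mat <- if (inherits(material, "material")) material else get_material(material)
  out <- numeric(length(energy_keV))
  for (el in names(mat$composition)) {
    g <- element_xsec(el)
    contrib <- switch(kind,
      photo = loglog_interp(g$energy_keV, g$photo_cm2_g, energy_keV),
      incoh = loglog_interp(g$energy_keV, g$incoh_cm2_g, energy_keV),
      total = loglog_interp(g$energy_keV, g$photo_cm2_g, energy_keV) +
              loglog_interp(g$energy_keV, g$incoh_cm2_g, energy_keV))
    out <- out + mat$composition[[el]] * contrib
  }
  out
}

#' Linear attenuation coefficient of a material
#'
#' @inheritParams mass_attenuation
#' @return Linear attenuation coefficient(s), 1/cm.
#' @examples
#' mu_linear("lead", 140)  # ~26 /cm at the Tc-99m line
#' @export
mu_linear <- function(material, energy_keV, kind = "total") {
  mat <- if (inherits(material, "material")) material else get_material(material)
  mat$density * mass_attenuation(mat, energy_keV, kind)
}

# attenuation table for the transport kernel: linear mu on the union of the
# element grids of the material (preserves absorption-edge refinement)
material_mu_table <- function(material) {
  mat <- if (inherits(material, "material")) material else get_material(material)
  key <- paste0("mu_", mat$name)
  cached(key, function() {
    grids <- lapply(names(mat$composition), function(el) element_xsec(el)$energy_keV)
    e <- sort(unique(unlist(grids)))
    list(energy_keV = e,
         mu_photo = mat$density * mass_attenuation(mat, e, "photo"),
         mu_incoh = mat$density * mass_attenuation(mat, e, "incoh"))
  })
}

# a zero-attenuation medium (used by narrow-beam mode)
vacuum_mu_table <- function() {
  list(energy_keV = c(15, 700), mu_photo = c(0, 0), mu_incoh = c(0, 0))
}
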
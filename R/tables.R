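# Physical data tables: radionuclide constants, barrier materials, Archer
# fit parameters and recommended occupancy factors. Every other module reads
# physical constants only through the accessors defined here.

read_table_csv <- function(name) {
  read.csv(nmshield_extdata("tables", name), stringsAsFactors = FALSE,
           comment.char = "#", check.names = TRUE)
}

nuclide_table <- function() cached("nuclides", function() read_table_csv("nuclides.csv"))
photon_line_table <- function() cached("lines", function() read_table_csv("photon_lines.csv"))
material_table <- function() cached("materials", function() read_table_csv("materials.csv"))
composition_table <- function() cached("compositions", function() read_table_csv("compositions.csv"))
archer_table <- function() cached("archer", function() read_table_csv("archer_params.csv"))
occupancy_table <- function() cached("occupancy", function() read_table_csv("occupancy.csv"))

# "Tc99m", "tc-99m", "99mTc" -> "Tc-99m"
normalize_nuclide <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- gsub("[^a-z0-9]", "", tolower(name))
  aliases <- c(
    "tc99m" = "Tc-99m", "99mtc" = "Tc-99m", "99tcm" = "Tc-99m",
    "i131" = "I-131", "131i" = "I-131",
    "lu177" = "Lu-177", "177lu" = "Lu-177",
    "f18" = "F-18", "18f" = "F-18"
  )
  if (!key %in% names(aliases)) {
    stop("unknown nuclide '", name, "'; supported nuclides are ",
         "Tc-99m, F-18, I-131, Lu-177", call. = FALSE)
  }
  unname(aliases[[key]])
}

normalize_material <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- gsub("[^a-z0-9]", "", tolower(name))
  aliases <- c(
    "lead" = "lead", "pb" = "lead",
    "gypsum" = "gypsum", "wallboard" = "gypsum", "drywall" = "gypsum",
    "glass" = "glass",
    "air" = "air",
    "muscle" = "muscle", "tissue" = "muscle",
    "lwconcrete" = "LW concrete", "concretelw" = "LW concrete",
    "lightweightconcrete" = "LW concrete",
    "nwconcrete" = "NW concrete", "concretenw" = "NW concrete",
    "normalweightconcrete" = "NW concrete", "concrete" = "NW concrete",
    "a514steel" = "A514 steel", "514steel" = "A514 steel",
    "steel" = "A514 steel", "steel514" = "A514 steel",
    "iron" = "iron", "fe" = "iron"
  )
  if (!key %in% names(aliases)) {
    stop("unknown material '", name, "'; known materials: ",
         paste(material_table()$name, collapse = ", "), call. = FALSE)
  }
  unname(aliases[[key]])
}

#' Look up the physical constants of a supported radionuclide
#'
#' Returns the shipped record for one of the four supported radionuclides:
#' half-life, decay mode, exposure-rate (gamma) constant at 1 cm, f-factor
#' (exposure-to-tissue-dose conversion) and the dominant photon emission
#' lines (every line above 15 keV energy and 100 ppm abundance).
#'
#' @param name Nuclide identifier. Case-insensitive; common alias spellings
#'   such as `"Tc99m"`, `"tc-99m"` or `"99mTc"` are accepted.
#' @return An object of class `nuclide`: a list with elements `name`,
#'   `half_life_value`, `half_life_unit`, `half_life_hours`, `decay_mode`,
#'   `gamma_constant` (R cm^2 / (mCi h)), `f_factor` (cGy/R) and
#'   `photon_lines` (data frame with `energy_keV`, `yield` per decay).
#' @examples
#' lu <- get_nuclide("Lu-177")
#' lu$gamma_constant  # 0.181 R cm^2 / (mCi h)
#' @export
get_nuclide <- function(name) {
  nm <- normalize_nuclide(name)
  tab <- nuclide_table()
  row <- tab[tab$name == nm, ]
  lines <- photon_line_table()
  lines <- lines[lines$nuclide == nm, c("energy_keV", "yield")]
  rownames(lines) <- NULL
  unit_h <- c(h = 1, d = 24, min = 1 / 60)
  structure(list(
    name = nm,
    half_life_value = row$half_life_value,
    half_life_unit = row$half_life_unit,
    half_life_hours = row$half_life_value * unit_h[[row$half_life_unit]],
    decay_mode = row$decay_mode,
    gamma_constant = row$gamma_constant_R_cm2_per_mCi_h,
    f_factor = row$f_factor_cGy_per_R,
    photon_lines = lines
  ), class = "nuclide")
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide %s>  T1/2 = %g %s,  Gamma = %g R cm2/(mCi h),  f = %g cGy/R\n",
              x$name, x$half_life_value, x$half_life_unit,
              x$gamma_constant, x$f_factor))
  cat(sprintf("  photon lines: %s\n",
              paste(sprintf("%g keV (%g%%)", x$photon_lines$energy_keV,
                            100 * x$photon_lines$yield), collapse = ", ")))
  invisible(x)
}

#' Construct an Archer parameter triple
#'
#' The broad-beam Archer model describes transmission through a barrier of
#' thickness `x` (mm) as
#' `T(x) = ((1 + beta/alpha) * exp(alpha*gamma*x) - beta/alpha)^(-1/gamma)`.
#' `alpha` (1/mm) is the asymptotic attenuation coefficient at large depth,
#' `beta` (1/mm) controls low-thickness curvature (it may be negative), and
#' `gamma` is a dimensionless shape exponent.
#'
#' @param alpha,beta,gamma Model parameters; `alpha > 0`, `gamma > 0`.
#' @param nuclide,material Optional identifiers recording what the triple
#'   describes.
#' @param source Provenance tag, e.g. `"this report"`, `"TG-108"`, `"fit"`.
#' @return An object of class `archer_params`.
#' @export
archer_params <- function(alpha, beta, gamma, nuclide = NA_character_,
                          material = NA_character_, source = "user") {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma),
            length(alpha) == 1L, length(beta) == 1L, length(gamma) == 1L)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (!is.finite(beta)) stop("beta must be finite", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 nuclide = nuclide, material = material, source = source),
            class = "archer_params")
}

#' @export
print.archer_params <- function(x, ...) {
  cat(sprintf("<archer_params %s / %s [%s]>  alpha = %g /mm, beta = %g /mm, gamma = %g\n",
              x$nuclide, x$material, x$source, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Look up the published Archer parameters for a nuclide-material pair
#'
#' Thicknesses are in millimetres of the named barrier material. Gypsum is
#' not available for F-18 and I-131: in practical thicknesses it offers
#' negligible attenuation of their photons and no parameters were fitted.
#'
#' @inheritParams get_nuclide
#' @param material Barrier material identifier (see [get_material()]).
#' @param source Parameter provenance. The default `"this report"` selects
#'   the fitted parameters of the underlying study; `"TG-108"` selects the
#'   legacy PET-shielding comparison rows (F-18 only).
#' @return An [archer_params()] object.
#' @examples
#' get_archer_params("Lu-177", "lead")
#' @export
get_archer_params <- function(nuclide, material, source = "this report") {
  nm <- normalize_nuclide(nuclide)
  source <- match.arg(source, c("this report", "TG-108"))
  mat <- normalize_material(material)
  tab <- archer_table()
  hit <- tab[tab$nuclide == nm & tab$material == mat & tab$source == source, ]
  if (nrow(hit) == 0L) {
    have <- tab[tab$source == source, ]
    if (nm %in% c("F-18", "I-131") && mat == "gypsum") {
      stop("no Archer parameters for ", nm, " through gypsum: gypsum offers ",
           "negligible attenuation for this nuclide and was excluded as a ",
           "significant barrier material", call. = FALSE)
    }
    stop("no Archer parameters for (", nm, ", ", mat, ") with source '",
         source, "'; available pairs: ",
         paste(sprintf("%s/%s", have$nuclide, have$material), collapse = ", "),
         call. = FALSE)
  }
  archer_params(hit$alpha_per_mm, hit$beta_per_mm, hit$gamma_exp,
                nuclide = nm, material = mat, source = source)
}

#' All published nuclide-material Archer pairs
#'
#' @param source Provenance tag filter, as in [get_archer_params()].
#' @return Data frame with columns `nuclide`, `material`, `alpha`, `beta`,
#'   `gamma`, `source`.
#' @export
list_archer_pairs <- function(source = "this report") {
  tab <- archer_table()
  tab <- tab[tab$source == source, ]
  data.frame(nuclide = tab$nuclide, material = tab$material,
             alpha = tab$alpha_per_mm, beta = tab$beta_per_mm,
             gamma = tab$gamma_exp, source = tab$source,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Look up a barrier material
#'
#' @param name Material identifier; case-insensitive with common aliases
#'   (`"Pb"`, `"514 steel"`, `"drywall"`, ...). Lead is a pure-element
#'   addition (density 11.35 g/cm^3) to the simulated material set and is
#'   flagged by `source = "added"`.
#' @return An object of class `material`: list with `name`, `density`
#'   (g/cm^3), `composition` (named numeric vector of element mass
#'   fractions) and `source`.
#' @examples
#' get_material("gypsum")$composition[["Ca"]]
#' @export
get_material <- function(name) {
  nm <- normalize_material(name)
  tab <- material_table()
  row <- tab[tab$name == nm, ]
  if (nrow(row) == 0L) {
    stop("unknown material '", name, "'; known materials: ",
         paste(tab$name, collapse = ", "), call. = FALSE)
  }
  comp <- composition_table()
  comp <- comp[comp$material == nm, ]
  structure(list(
    name = nm,
    density = row$density_g_cm3,
    composition = setNames(comp$mass_fraction, comp$element),
    source = row$source
  ), class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material %s>  density %g g/cm3\n", x$name, x$density))
  cat("  composition:",
      paste(sprintf("%s %.6g", names(x$composition), x$composition),
            collapse = ", "), "\n")
  invisible(x)
}

#' Recommended occupancy factor for an area of a nuclear medicine department
#'
#' Matches `area_key` against the shipped table of recommended occupancy
#' factors (adapted from the NCRP diagnostic-shielding convention). Matching
#' is case-insensitive against the comma-separated area phrases; a singular
#' query matches its plural ("office" matches "offices").
#'
#' @param area_key Keyword or phrase, e.g. `"office"`, `"corridor"`,
#'   `"stairway"`.
#' @return The occupancy factor, a fraction in (0, 1].
#' @examples
#' get_occupancy("office")    # 1
#' get_occupancy("corridor")  # 1/5
#' @export
get_occupancy <- function(area_key) {
  stopifnot(is.character(area_key), length(area_key) == 1L)
  tab <- occupancy_table()
  norm <- function(s) gsub("^\\s+|\\s+$", "", tolower(s))
  strip_plural <- function(s) sub("s$", "", s)
  q <- strip_plural(norm(area_key))
  phrases <- lapply(seq_len(nrow(tab)), function(i) {
    norm(strsplit(tab$area_description[i], ",")[[1]])
  })
  # exact phrase match (plural-insensitive) first
  for (i in seq_along(phrases)) {
    if (q %in% strip_plural(phrases[[i]])) return(tab$occupancy_factor[i])
  }
  # unique substring match second
  hits <- which(vapply(phrases, function(ph) any(grepl(q, ph, fixed = TRUE)),
                       logical(1)))
  if (length(hits) == 1L) return(tab$occupancy_factor[hits])
  if (length(hits) > 1L) {
    stop("ambiguous area key '", area_key, "'; matches: ",
         paste(tab$area_description[hits], collapse = " | "), call. = FALSE)
  }
  stop("unknown area key '", area_key, "'; valid areas:\n  ",
       paste(tab$area_description, collapse = "\n  "), call. = FALSE)
}

#' Write the shipped data tables to CSV files for audit
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
dump_tables <- function(dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c("nuclides.csv", "photon_lines.csv", "materials.csv",
             "compositions.csv", "archer_params.csv", "occupancy.csv")
  out <- character(0)
  for (f in files) {
    dest <- file.path(dir, f)
    file.copy(nmshield_extdata("tables", f), dest, overwrite = TRUE)
    out <- c(out, dest)
  }
  invisible(out)
}
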
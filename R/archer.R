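# Closed-form broad-beam transmission: the Archer equation, its inverse and
# fractional value layers.

as_archer <- function(params) {
  if (inherits(params, "archer_params")) return(params)
  stop("'params' must be an archer_params object (see get_archer_params())",
       call. = FALSE)
}

#' Broad-beam transmission through a barrier (Archer equation)
#'
#' Evaluates
#' `T(x) = ((1 + beta/alpha) * exp(alpha*gamma*x) - beta/alpha)^(-1/gamma)`
#' for barrier thickness `x` in millimetres. `T(0) = 1` exactly and `T` is
#' strictly decreasing in `x`, approaching `exp(-alpha*x)` asymptotically at
#' large depth.
#'
#' @param params An [archer_params()] object.
#' @param x_mm Barrier thickness(es), mm, `>= 0`.
#' @return Transmission fraction(s) in (0, 1].
#' @examples
#' p <- get_archer_params("Lu-177", "lead")
#' archer_transmission(p, 0.511)  # ~0.5: the half-value layer
#' @export
archer_transmission <- function(params, x_mm) {
  p <- as_archer(params)
  if (!is.numeric(x_mm) || any(!is.finite(x_mm))) {
    stop("thickness must be finite and numeric", call. = FALSE)
  }
  if (any(x_mm < 0)) stop("thickness must be >= 0", call. = FALSE)
  r <- p$beta / p$alpha
  u <- p$alpha * p$gamma * x_mm
  # ln[(1+r) e^u - r], computed as u + ln(1+r) + ln(1 - r e^-u/(1+r)) when
  # e^u would overflow
  lnb <- numeric(length(u))
  big <- u > 30
  lnb[big] <- u[big] + log1p(r) + log1p(-r * exp(-u[big]) / (1 + r))
  lnb[!big] <- log((1 + r) * exp(u[!big]) - r)
  tr <- exp(-lnb / p$gamma)
  tr[x_mm == 0] <- 1
  tr
}

#' Barrier thickness required for a target transmission (inverse Archer)
#'
#' Solves the Archer equation for thickness:
#' `x = 1/(alpha*gamma) * ln((T^-gamma + beta/alpha) / (1 + beta/alpha))`.
#'
#' @param params An [archer_params()] object.
#' @param transmission Target transmission fraction(s), in (0, 1].
#' @return Required thickness(es) in mm; 0 when `transmission = 1`.
#' @examples
#' p <- get_archer_params("Lu-177", "lead")
#' archer_thickness(p, 0.166)  # 1.48 mm
#' @export
archer_thickness <- function(params, transmission) {
  p <- as_archer(params)
  if (!is.numeric(transmission) || any(!is.finite(transmission))) {
    stop("transmission must be finite and numeric", call. = FALSE)
  }
  if (any(transmission <= 0 | transmission > 1)) {
    stop("transmission must be in (0, 1]", call. = FALSE)
  }
  r <- p$beta / p$alpha
  u <- -p$gamma * log(transmission)        # = ln(T^-gamma) >= 0
  # ln(T^-gamma + r) computed stably when T^-gamma overflows
  lnn <- ifelse(u > 300, u + log1p(r * exp(-u)), log(exp(u) + r))
  x <- (lnn - log1p(r)) / (p$alpha * p$gamma)
  x[transmission == 1] <- 0
  pmax(x, 0)
}

#' Fractional value layers of a nuclide-material pair
#'
#' Thicknesses transmitting 1/2 (HVL), 1/4 (QVL), 1/10 (TVL), 1/100 (CVL)
#' and 1/1000 (MVL) of the incident broad-beam dose, from the inverse Archer
#' equation.
#'
#' @param params An [archer_params()] object.
#' @return Named numeric vector `c(HVL, QVL, TVL, CVL, MVL)`, mm.
#' @examples
#' value_layers(get_archer_params("Tc-99m", "lead"))
#' @export
value_layers <- function(params) {
  fr <- c(HVL = 0.5, QVL = 0.25, TVL = 0.1, CVL = 0.01, MVL = 0.001)
  setNames(archer_thickness(params, unname(fr)), names(fr))
}

#' Tabulate fractional value layers for many nuclide-material pairs
#'
#' @param nuclides Character vector of nuclide identifiers; default all four.
#' @param materials Character vector of material identifiers; default all
#'   barrier materials with published parameters.
#' @param strict If `TRUE`, a requested pair without published parameters is
#'   an error; if `FALSE` (default) such pairs are skipped, so the default
#'   full grid reproduces the published 21-row layout (no gypsum row for
#'   F-18 or I-131, no glass row for F-18).
#' @return Data frame with columns `nuclide`, `material`,
#'   `HVL_mm`, `QVL_mm`, `TVL_mm`, `CVL_mm`, `MVL_mm`.
#' @export
value_layer_table <- function(nuclides = c("Tc-99m", "Lu-177", "I-131", "F-18"),
                              materials = c("lead", "gypsum", "LW concrete",
                                            "NW concrete", "A514 steel", "glass"),
                              strict = FALSE) {
  rows <- list()
  for (nuc in nuclides) {
    for (mat in materials) {
      p <- tryCatch(get_archer_params(nuc, mat), error = function(e) e)
      if (inherits(p, "error")) {
        if (strict) stop(p)
        next
      }
      vl <- value_layers(p)
      rows[[length(rows) + 1L]] <- data.frame(
        nuclide = p$nuclide, material = p$material,
        HVL_mm = vl[["HVL"]], QVL_mm = vl[["QVL"]], TVL_mm = vl[["TVL"]],
        CVL_mm = vl[["CVL"]], MVL_mm = vl[["MVL"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
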
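# Fitting the Archer functional form to transmission-curve data, and
# generating synthetic noisy curves for parameter-recovery testing.
#
# The three Archer parameters are only weakly identifiable: different
# (alpha, beta, gamma) triples can describe visually identical curves.
# Fit quality is therefore always judged in curve space (predicted
# transmission), never by comparing parameter triples.

#' Construct a transmission curve
#'
#' @param thickness_mm Barrier thicknesses, mm; non-negative, strictly
#'   increasing.
#' @param transmission Transmission fractions in (0, 1].
#' @param sd Optional per-point standard deviations of `transmission`.
#' @param nuclide,material Optional identifiers.
#' @return Object of class `transmission_curve`: a data frame with columns
#'   `thickness_mm`, `transmission` and optionally `sd`, plus attributes
#'   `nuclide` and `material`.
#' @export
transmission_curve <- function(thickness_mm, transmission, sd = NULL,
                               nuclide = NA_character_,
                               material = NA_character_) {
  stopifnot(is.numeric(thickness_mm), is.numeric(transmission),
            length(thickness_mm) == length(transmission))
  if (length(thickness_mm) > 0) {
    if (any(thickness_mm < 0)) stop("thicknesses must be >= 0", call. = FALSE)
    if (any(diff(thickness_mm) <= 0)) {
      stop("thicknesses must be strictly increasing", call. = FALSE)
    }
    if (any(transmission <= 0 | transmission > 1)) {
      stop("transmissions must be in (0, 1]", call. = FALSE)
    }
  }
  df <- data.frame(thickness_mm = thickness_mm, transmission = transmission)
  if (!is.null(sd)) {
    stopifnot(length(sd) == length(thickness_mm))
    df$sd <- sd
  }
  structure(df, nuclide = nuclide, material = material,
            class = c("transmission_curve", "data.frame"))
}

#' Read/write a transmission curve as CSV
#'
#' The CSV has columns `thickness_mm`, `transmission` and optionally `sd`.
#'
#' @param path File path.
#' @param nuclide,material Optional identifiers attached on read.
#' @return `read_curve` returns a [transmission_curve()].
#' @export
read_curve <- function(path, nuclide = NA_character_,
                       material = NA_character_) {
  if (!file.exists(path)) stop("curve file not found: ", path, call. = FALSE)
  df <- read.csv(path, comment.char = "#")
  if (!all(c("thickness_mm", "transmission") %in% names(df))) {
    stop("curve CSV needs columns thickness_mm, transmission", call. = FALSE)
  }
  transmission_curve(df$thickness_mm, df$transmission, sd = df$sd,
                     nuclide = nuclide, material = material)
}

#' @param curve A [transmission_curve()].
#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

# deterministic seed-scoped RNG evaluation
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic transmission curve from Archer parameters
#'
#' Evaluates the Archer equation on a thickness grid and applies
#' mean-one multiplicative lognormal noise with coefficient of variation
#' `noise_cv` (`sigma^2 = log(1 + cv^2)`). With `noise_cv = 0` the exact
#' model values are returned. Values are capped at 1 so the result remains
#' a valid transmission curve.
#'
#' @param params An [archer_params()] object.
#' @param thicknesses_mm Thickness grid, mm (strictly increasing, `>= 0`).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed; required so curves are reproducible.
#' @return A [transmission_curve()] with an `sd` column (`noise_cv * T`).
#' @export
generate_synthetic_curve <- function(params, thicknesses_mm, noise_cv = 0,
                                     seed) {
  p <- as_archer(params)
  stopifnot(is.numeric(noise_cv), length(noise_cv) == 1L, noise_cv >= 0)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  tr <- archer_transmission(p, thicknesses_mm)
  if (noise_cv > 0) {
    sigma <- sqrt(log(1 + noise_cv^2))
    fac <- with_seed(seed, exp(rnorm(length(tr), -sigma^2 / 2, sigma)))
    tr <- pmin(tr * fac, 1)
  }
  transmission_curve(thicknesses_mm, tr, sd = noise_cv * tr,
                     nuclide = p$nuclide, material = p$material)
}

#' A default thickness grid spanning the useful range of a parameter set
#'
#' Geometric grid from one fifth of the half-value layer to the
#' thousandth-value layer.
#'
#' @param params An [archer_params()] object.
#' @param n Number of points.
#' @return Numeric vector of thicknesses, mm.
#' @export
default_thickness_grid <- function(params, n = 12) {
  vl <- value_layers(params)
  exp(seq(log(vl[["HVL"]] / 5), log(vl[["MVL"]]), length.out = n))
}

# ln T under the Archer model, parameterized by (log alpha, beta, log gamma);
# returns a large finite penalty outside the valid region beta > -alpha so
# the optimizer is steered back without NaN residuals
archer_lnT <- function(theta, x) {
  a <- exp(theta[[1]]); b <- theta[[2]]; g <- exp(theta[[3]])
  if (!is.finite(a) || !is.finite(b) || !is.finite(g) || b <= -a) {
    return(rep(1e6, length(x)))
  }
  r <- b / a
  u <- a * g * x
  lnb <- numeric(length(u))
  big <- u > 30
  lnb[big] <- u[big] + log1p(r) + log1p(-r * exp(-u[big]) / (1 + r))
  lnb[!big] <- log(pmax((1 + r) * exp(u[!big]) - r, 1e-300))
  -lnb / g
}

#' Fit the Archer model to a transmission curve
#'
#' Nonlinear least squares on ln(T) (transmission typically spans several
#' decades, so log-space fitting weights the whole curve evenly).
#' Levenberg-Marquardt with five deterministic multi-starts; alpha and gamma
#' are kept positive through a log parameterization, beta is unconstrained.
#' If two starts converge to curves within 1e-8 rms of each other the one
#' with the smaller |beta| is kept.
#'
#' @param curve A [transmission_curve()] with at least 4 points (3 free
#'   parameters).
#' @param init Optional [archer_params()] used as the first start.
#' @param n_starts Number of multi-starts (>= 1).
#' @return Object of class `archer_fit`: list with `params` (an
#'   [archer_params()] with `source = "fit"`), `rms_log_residual`,
#'   `converged`, `n_points` and `diagnostics` (per-start summary).
#'   Non-convergence is reported through `converged = FALSE`, not an error.
#' @examples
#' p <- get_archer_params("Tc-99m", "lead")
#' cv <- generate_synthetic_curve(p, c(0.1, 0.25, 0.5, 1, 1.5, 2, 2.5, 3),
#'                                noise_cv = 0, seed = 1)
#' fit_archer(cv)
#' @export
fit_archer <- function(curve, init = NULL, n_starts = 5) {
  if (!inherits(curve, "transmission_curve")) {
    stop("'curve' must be a transmission_curve", call. = FALSE)
  }
  x <- curve$thickness_mm
  tr <- curve$transmission
  if (nrow(curve) < 4L) {
    stop("at least 4 points are needed to fit 3 parameters", call. = FALSE)
  }
  if (all(tr >= 1)) {
    stop("degenerate curve: all transmissions are 1", call. = FALSE)
  }
  lnT <- log(tr)
  ord <- order(x)   # fit is invariant to point order
  x <- x[ord]; lnT <- lnT[ord]

  # heuristic initialization: asymptotic slope from the last two points
  n <- length(x)
  a0 <- max((lnT[n - 1] - lnT[n]) / (x[n] - x[n - 1]), 1e-6)
  b0 <- a0 * max(exp(-lnT[1]) - 1, 0.01)
  starts <- list(c(log(a0), b0, log(1)))
  for (g0 in c(0.3, 3, 0.5, 10, 0.1, 30)) {
    starts[[length(starts) + 1L]] <- c(log(a0), b0, log(g0))
  }
  if (!is.null(init)) {
    ip <- as_archer(init)
    starts <- c(list(c(log(ip$alpha), ip$beta, log(ip$gamma))), starts)
  }
  starts <- starts[seq_len(min(length(starts), max(1L, n_starts)))]

  resid_fn <- function(theta) archer_lnT(theta, x) - lnT
  best <- NULL
  diag_rows <- list()
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rms <- sqrt(mean(fit$fvec^2))
    ok <- fit$info %in% 1:4
    diag_rows[[length(diag_rows) + 1L]] <- data.frame(
      start = i, rms_log_residual = rms, converged = ok,
      alpha = exp(fit$par[[1]]), beta = fit$par[[2]],
      gamma = exp(fit$par[[3]]))
    better <- is.null(best) || rms < best$rms - 1e-8 ||
      (abs(rms - best$rms) <= 1e-8 && abs(fit$par[[2]]) < abs(best$par[[2]]))
    if (better) best <- list(par = fit$par, rms = rms, ok = ok)
  }
  if (is.null(best)) {
    stop("all fit starts failed to evaluate", call. = FALSE)
  }
  params <- archer_params(exp(best$par[[1]]), best$par[[2]],
                          exp(best$par[[3]]),
                          nuclide = attr(curve, "nuclide"),
                          material = attr(curve, "material"),
                          source = "fit")
  structure(list(params = params,
                 rms_log_residual = best$rms,
                 converged = isTRUE(best$ok),
                 n_points = n,
                 diagnostics = do.call(rbind, diag_rows)),
            class = "archer_fit")
}

#' @export
print.archer_fit <- function(x, ...) {
  cat(sprintf("<archer_fit>  %d points, rms log-residual %.3g, converged: %s\n",
              x$n_points, x$rms_log_residual, x$converged))
  print(x$params)
  invisible(x)
}

#' Maximum relative transmission difference between two fits
#'
#' Fit equivalence is declared in curve space: two parameter triples are
#' equivalent when their predicted transmissions agree over the thickness
#' range of interest, regardless of how different the triples look.
#'
#' @param a,b [archer_fit()] results or [archer_params()] objects for the
#'   same nuclide-material pair.
#' @param grid_mm Thicknesses (mm) over which to compare.
#' @return `max over grid of |T_a - T_b| / T_b`.
#' @export
compare_fits <- function(a, b, grid_mm) {
  pa <- if (inherits(a, "archer_fit")) a$params else as_archer(a)
  pb <- if (inherits(b, "archer_fit")) b$params else as_archer(b)
  same <- function(x, y) is.na(x) || is.na(y) || identical(x, y)
  if (!same(pa$nuclide, pb$nuclide) || !same(pa$material, pb$material)) {
    stop("fits describe different nuclide-material pairs: ",
         pa$nuclide, "/", pa$material, " vs ", pb$nuclide, "/", pb$material,
         call. = FALSE)
  }
  ta <- archer_transmission(pa, grid_mm)
  tb <- archer_transmission(pb, grid_mm)
  max(abs(ta - tb) / tb)
}
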
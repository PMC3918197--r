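# Literature defaults for the pre-TG-43 Cs-137 point-source formalism.
# Exposure-rate constant (R cm^2 mCi^-1 h^-1), roentgen-to-cGy f-factor,
# and the Meisberger third-order tissue attenuation/scatter polynomial
# T(r) = A + B r + C r^2 + D r^3 for Cs-137 (Meisberger et al. 1968).
.CS137_GAMMA <- 3.28
.CS137_F_FACTOR <- 0.962
.CS137_MEISBERGER <- c(1.0091, -9.015e-3, -3.459e-4, -2.817e-5)
.T_RANGE_CM <- c(0.5, 10)

#' Legacy point-source dose-calculation parameters
#'
#' Parameter set for the pre-TG-43 formalism used by older treatment
#' planning systems: exposure-rate constant Gamma, apparent activity per
#' pellet, roentgen-to-dose f-factor and a polynomial tissue
#' attenuation/scatter correction T(r). The engine is isotropic by
#' construction: no anisotropy, no applicator or inter-pellet shielding.
#'
#' Defaults are standard literature values for Cs-137: Gamma = 3.28
#' R cm^2 mCi^-1 h^-1, f = 0.962 cGy/R, and the Meisberger third-order
#' polynomial. All are overridable; none is specific to any one planning
#' system's internals. T(r) is supported on 0.5-10 cm and clamped (with a
#' warning) outside.
#'
#' @param exposure_rate_constant Gamma, R cm^2 mCi^-1 h^-1.
#' @param activity_mCi Apparent activity per pellet, mCi.
#' @param f_factor Roentgen-to-dose conversion, cGy/R.
#' @param attenuation_coeffs Polynomial coefficients of T(r), ascending
#'   powers of r (cm).
#' @return An object of class `legacy_parameters`.
#' @export
legacy_parameters <- function(exposure_rate_constant = .CS137_GAMMA,
                              activity_mCi = 1,
                              f_factor = .CS137_F_FACTOR,
                              attenuation_coeffs = .CS137_MEISBERGER) {
  vals <- c(exposure_rate_constant, activity_mCi, f_factor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("Gamma, activity and f-factor must all be finite and > 0")
  attenuation_coeffs <- as.numeric(attenuation_coeffs)
  if (length(attenuation_coeffs) < 1L || any(!is.finite(attenuation_coeffs)))
    stop("attenuation_coeffs must be finite")
  p <- structure(
    list(exposure_rate_constant = exposure_rate_constant,
         activity_mCi = activity_mCi,
         f_factor = f_factor,
         attenuation_coeffs = attenuation_coeffs),
    class = "legacy_parameters")
  rr <- seq(.T_RANGE_CM[1L], .T_RANGE_CM[2L], by = 0.1)
  if (any(.eval_T(p, rr) <= 0))
    stop(sprintf("T(r) must stay > 0 over the supported range [%g, %g] cm",
                 .T_RANGE_CM[1L], .T_RANGE_CM[2L]))
  p
}

# Horner evaluation of T(r), clamped to its validity range
.eval_T <- function(params, r, warn = FALSE) {
  rc <- pmin(pmax(r, .T_RANGE_CM[1L]), .T_RANGE_CM[2L])
  if (warn && any(rc != r))
    warning(sprintf("T(r) evaluated outside its validity range [%g, %g] cm; clamped",
                    .T_RANGE_CM[1L], .T_RANGE_CM[2L]))
  out <- 0
  for (c_k in rev(params$attenuation_coeffs)) out <- out * rc + c_k
  out
}

#' Legacy point-source dose rate
#'
#' The pre-TG-43 estimate: exposure rate from the exposure-rate constant,
#' activity and inverse square law, converted to dose with the f-factor and
#' corrected for tissue attenuation and scatter,
#' D(r) = f * Gamma * A * T(r) / r^2. Isotropic: no theta dependence.
#'
#' @param params A [legacy_parameters()].
#' @param r Distance(s) in cm, > 0.
#' @return Dose rate in cGy/h.
#' @export
legacy_dose_rate <- function(params, r) {
  stopifnot(inherits(params, "legacy_parameters"))
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("r must be finite and > 0")
  params$f_factor * params$exposure_rate_constant * params$activity_mCi *
    .eval_T(params, r, warn = TRUE) / r^2
}

#' Pellet-train dose rate by legacy superposition
#'
#' Simple superposition of isotropic point-source doses over the active
#' pellets: each contributes [legacy_dose_rate()] at its distance to the
#' point. No anisotropy and no applicator or inter-pellet attenuation —
#' the behaviour of pre-TG-43 planning systems this engine exists to be
#' compared against.
#'
#' @param config A [train_configuration()].
#' @param params A [legacy_parameters()]; the activity is per pellet,
#'   uniform across active pellets.
#' @param q Length-3 point (cm) or `n x 3` matrix of points.
#' @return Dose rate(s) in cGy/h; matrix-input points inside a pellet
#'   return `NA`, a single such point raises an error.
#' @export
legacy_train_dose <- function(config, params, q) {
  stopifnot(inherits(config, "train_configuration"),
            inherits(params, "legacy_parameters"))
  if (!any(config$active_flags))
    stop("configuration has no active pellets")
  one <- function(qi, masked_na) {
    if (any(!is.finite(qi))) stop("evaluation point must be finite")
    pol <- .train_polar(config, qi)
    if (any(pol$r < .PELLET_RADIUS_CM)) {
      if (masked_na) return(NA_real_)
      stop(sprintf("point (%g, %g, %g) lies inside an active pellet (masked)",
                   qi[1L], qi[2L], qi[3L]))
    }
    sum(legacy_dose_rate(params, pol$r))
  }
  .dedup_warnings({
    if (is.matrix(q)) {
      stopifnot(ncol(q) == 3L)
      vapply(seq_len(nrow(q)), function(i) one(q[i, ], TRUE), numeric(1))
    } else {
      one(as.numeric(q), FALSE)
    }
  })
}

#' Calibrate the legacy engine to a TG-43U1 source
#'
#' Scales the legacy per-pellet activity so that a single isolated pellet
#' gives the same dose rate as the TG-43U1 model at the reference point
#' (1 cm on the transverse axis). With physically matched engines the
#' remaining differences isolate what the legacy formalism ignores —
#' anisotropy and applicator/spacer shielding.
#'
#' @param params A [legacy_parameters()].
#' @param model A [source_model()].
#' @return `params` with `activity_mCi` rescaled.
#' @export
calibrate_legacy <- function(params, model) {
  stopifnot(inherits(params, "legacy_parameters"),
            inherits(model, "source_model"))
  target <- suppressWarnings(dose_rate(model, .TG43_R0, .TG43_THETA0))
  current <- legacy_dose_rate(params, .TG43_R0)
  if (current <= 0 || target <= 0)
    stop("cannot calibrate: non-positive reference dose rate")
  params$activity_mCi <- params$activity_mCi * target / current
  params
}

#' Read legacy parameters from file
#'
#' Sectioned dialect with a `[legacy]` section holding `gamma`,
#' `activity_mci`, `f_factor` and `t_coeffs` (whitespace- or
#' comma-separated ascending polynomial coefficients).
#'
#' @param path File path.
#' @return A [legacy_parameters()].
#' @export
read_legacy_parameters <- function(path) {
  if (!file.exists(path)) stop("legacy parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sec <- .split_sections(lines)
  if (is.null(sec$legacy)) stop("file ", path, ": missing [legacy] section")
  kv <- .parse_keyvals(sec$legacy, path)
  legacy_parameters(
    exposure_rate_constant = if (is.null(kv$gamma)) .CS137_GAMMA else kv$gamma,
    activity_mCi = if (is.null(kv$activity_mci)) 1 else kv$activity_mci,
    f_factor = if (is.null(kv$f_factor)) .CS137_F_FACTOR else kv$f_factor,
    attenuation_coeffs = if (is.null(kv$t_coeffs)) .CS137_MEISBERGER else kv$t_coeffs)
}

#' @export
print.legacy_parameters <- function(x, ...) {
  cat(sprintf("Legacy point-source parameters: Gamma = %g R cm^2/(mCi h), A = %g mCi, f = %g cGy/R\n",
              x$exposure_rate_constant, x$activity_mCi, x$f_factor))
  cat("  T(r) coefficients (ascending powers):",
      paste(format(x$attenuation_coeffs), collapse = ", "), "\n")
  invisible(x)
}
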
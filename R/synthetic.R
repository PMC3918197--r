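#' Specification of a synthetic single-pellet source
#'
#' Defines an analytic dose field with known TG-43U1 structure, used to
#' exercise the parameter-extraction path: a true dose-rate constant and
#' air-kerma strength, a smooth decreasing radial dose function, a smooth
#' anisotropy dip toward the poles, and optional multiplicative noise
#' emulating the relative uncertainty of Monte Carlo tallies.
#'
#' The radial shape is the quadratic
#' g(r) = 1 + c1 (r - 1) + c2 (r - 1)^2 (normalized to 1 at r0 = 1 cm by
#' construction) and the angular shape is
#' F(theta) = 1 - a0 |cos(theta)|^p (normalized to 1 at 90 degrees).
#' Defaults give the gentle few-percent-per-cm fall-off and ~10% polar dip
#' typical of an encapsulated Cs-137 pellet in water.
#'
#' @param lambda_true True dose-rate constant, cGy/h/U.
#' @param sk_true True air-kerma strength, U.
#' @param g_shape Numeric `c(c1, c2)` of the radial polynomial.
#' @param F_shape Numeric `c(a0, p)` of the anisotropy dip.
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   noise; 0 gives the exact analytic field.
#' @param seed Integer seed making noisy maps reproducible.
#' @return An object of class `synthetic_source_spec`.
#' @export
synthetic_source_spec <- function(lambda_true = 1.1, sk_true = 1.0,
                                  g_shape = c(-0.012, -4e-4),
                                  F_shape = c(0.10, 2),
                                  noise_cv = 0, seed = 1L) {
  if (!is.finite(lambda_true) || lambda_true <= 0) stop("lambda_true must be > 0")
  if (!is.finite(sk_true) || sk_true <= 0) stop("sk_true must be > 0")
  if (!is.finite(noise_cv) || noise_cv < 0) stop("noise_cv must be >= 0")
  if (length(g_shape) != 2L || length(F_shape) != 2L)
    stop("g_shape and F_shape must each have 2 parameters")
  if (F_shape[1L] < 0 || F_shape[1L] >= 1)
    stop("anisotropy dip amplitude must be in [0, 1)")
  structure(list(lambda_true = lambda_true, sk_true = sk_true,
                 g_shape = as.numeric(g_shape), F_shape = as.numeric(F_shape),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "synthetic_source_spec")
}

#' True radial dose function of a synthetic spec
#' @param spec A [synthetic_source_spec()].
#' @param r Radii, cm.
#' @return g(r), dimensionless.
#' @export
synthetic_g_true <- function(spec, r) {
  g <- 1 + spec$g_shape[1L] * (r - 1) + spec$g_shape[2L] * (r - 1)^2
  if (any(g <= 0)) stop("g_shape yields non-positive g(r) at requested radii")
  g
}

#' True anisotropy function of a synthetic spec
#' @param spec A [synthetic_source_spec()].
#' @param theta Angles, degrees.
#' @return F(theta), dimensionless (radius-independent by construction).
#' @export
synthetic_F_true <- function(spec, theta) {
  1 - spec$F_shape[1L] * abs(cos(theta * pi / 180))^spec$F_shape[2L]
}

#' Render a synthetic polar dose map
#'
#' Evaluates D(r, theta) = Sk * Lambda * (r0/r)^2 * g(r) * F(theta) on the
#' requested polar grid and, if `noise_cv > 0`, multiplies each sample by
#' mean-one log-normal noise (tally uncertainty is relative, hence
#' multiplicative). Rendering is deterministic for a fixed spec and seed
#' and does not disturb the caller's RNG state.
#'
#' @param spec A [synthetic_source_spec()].
#' @param radii Sample radii, cm.
#' @param angles Sample angles, degrees.
#' @return A [dose_map_polar()].
#' @export
render_dose_map <- function(spec, radii = 1:10, angles = seq(15, 165, by = 15)) {
  stopifnot(inherits(spec, "synthetic_source_spec"))
  radii <- as.numeric(radii); angles <- as.numeric(angles)
  g <- synthetic_g_true(spec, radii)
  Fv <- synthetic_F_true(spec, angles)
  D <- spec$sk_true * spec$lambda_true *
    outer(g / radii^2, Fv)
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    noise <- .with_local_seed(spec$seed, {
      matrix(stats::rlnorm(length(D), meanlog = -sdlog^2 / 2, sdlog = sdlog),
             nrow(D), ncol(D))
    })
    D <- D * noise
  }
  dose_map_polar(radii, angles, D)
}

#' Render synthetic in-air kerma samples
#'
#' Ideal point-source kerma, kerma(d) = Sk / d^2, with optional mean-one
#' multiplicative log-normal noise — the input the air-kerma strength
#' estimator is designed for.
#'
#' @param spec A [synthetic_source_spec()]; `sk_true` sets the constant.
#' @param distances_cm Sample distances, cm (default 0.5 to 150).
#' @return A [kerma_samples()].
#' @export
render_kerma_samples <- function(spec, distances_cm = c(0.5, 1, 2, 5, 10, 20,
                                                        50, 100, 150)) {
  stopifnot(inherits(spec, "synthetic_source_spec"))
  k <- spec$sk_true / distances_cm^2
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    k <- k * .with_local_seed(spec$seed + 1L, {
      stats::rlnorm(length(k), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
  }
  kerma_samples(distances_cm, k)
}

# run expr under a fixed seed without clobbering the global RNG stream
.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Packaged Cs-137 pellet parameter set
#'
#' Loads the parameter file shipped with the package for a Cs-137
#' Selectron pellet in the first (tip-most) slot of a cylindrical vaginal
#' applicator: a 10-node radial dose function over 1-10 cm and a 3-radius
#' by 11-angle anisotropy table over 15-165 degrees. The anisotropy is
#' asymmetric about 90 degrees because the applicator and the neighbouring
#' spacer pellets shield the two polar directions differently.
#'
#' The dose-rate constant and air-kerma strength in the file are
#' placeholder values of 1, so absolute dose rates from this model are in
#' units of Sk * Lambda; ratio-based comparisons are unaffected. Replace
#' them with calibrated values for absolute work.
#'
#' @return A [source_model()].
#' @examples
#' m <- cs137_pellet_model()
#' eval_g(m$radial_table, 10)                 # 0.865
#' eval_F(m$anisotropy_table, 3, 15)          # 0.903
#' @export
cs137_pellet_model <- function() {
  path <- system.file("extdata", "cs137_pellet_pos1.txt",
                      package = "pelletdose", mustWork = TRUE)
  load_parameter_file(path)
}
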
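#' Point-source geometry function
#'
#' The point-source approximation of the TG-43U1 geometry function is the
#' inverse square law, Gp(r) = 1/r^2 (cm^-2). Spherical LDR pellets of
#' 2.5 mm diameter are well represented by it at clinical distances, and the
#' line-source variant is deliberately not provided.
#'
#' @param r Distance(s) in cm; must be > 0.
#' @return 1/r^2, in cm^-2.
#' @export
geometry_point <- function(r) {
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("r must be finite and > 0")
  1 / r^2
}

# TG-43U1 reference geometry: r0 = 1 cm on the transverse axis (theta0 = 90)
.TG43_R0 <- 1.0
.TG43_THETA0 <- 90.0

#' Single-source TG-43U1 dose rate
#'
#' Evaluates the TG-43U1 dose-rate equation with the point-source geometry
#' function:
#'
#' D(r, theta) = Sk * Lambda * \[Gp(r) / Gp(r0)\] * g(r) * F(r, theta)
#'
#' with r0 = 1 cm and theta0 = 90 degrees. At the reference point the result
#' is exactly Sk * Lambda.
#'
#' @param source A [source_model()].
#' @param r Distance(s) from the source center in cm, > 0.
#' @param theta Polar angle(s) in degrees in \[0, 180\], measured from the
#'   applicator's longitudinal axis.
#' @return Dose rate in cGy/h (vectorized over `r` and `theta`).
#' @examples
#' m <- cs137_pellet_model()
#' dose_rate(m, r = 2, theta = 90)   # Sk*Lambda placeholders are 1 => 0.2495
#' @export
dose_rate <- function(source, r, theta) {
  stopifnot(inherits(source, "source_model"))
  source$air_kerma_strength * source$dose_rate_constant *
    (geometry_point(r) / geometry_point(.TG43_R0)) *
    eval_g(source$radial_table, r) *
    eval_F(source$anisotropy_table, r, theta)
}

#' Extract TG-43U1 parameters from a sampled dose distribution
#'
#' Inverts the TG-43U1 equation on a polar dose-rate map sampled around a
#' single source (e.g. a Monte Carlo dose distribution scored on a fine
#' lattice): the dose-rate constant is the reference-point dose rate per
#' unit air-kerma strength, the radial dose function is the transverse
#' profile with inverse square divided out, and the anisotropy function is
#' each radius's angular profile normalized to its transverse value.
#'
#' The reference point (1 cm, 90 deg) is snapped to the nearest sampled
#' node within `tol_r` / `tol_theta`, since a scoring lattice need not
#' contain it exactly; the returned tables are normalized at the snapped
#' node and therefore satisfy the table invariants by construction.
#'
#' @param map A [dose_map_polar()].
#' @param sk Air-kerma strength Sk in U used to normalize Lambda; > 0.
#' @param tol_r Snap tolerance for the reference radius, cm (default 0.05).
#' @param tol_theta Snap tolerance for the reference angle, degrees
#'   (default 1).
#' @param smooth_g_order Optional integer: fit the inverse-square-corrected
#'   transverse profile with a polynomial of this order in r and tabulate
#'   the fitted radial dose function, instead of taking the raw per-radius
#'   ratios. `NULL` (default) keeps the exact node-by-node inversion.
#'   Polynomial fits of g(r) are the standard way to tabulate noisy
#'   Monte Carlo radial data; use an order well below the number of
#'   sampled radii.
#' @param label Label for the returned model.
#' @return A [source_model()] with Lambda, g(r) at the map's radii and
#'   F(r, theta) on the map's interior angular grid, and
#'   `air_kerma_strength` set to `sk`.
#' @export
extract_parameters <- function(map, sk, tol_r = 0.05, tol_theta = 1.0,
                               smooth_g_order = NULL, label = "extracted") {
  stopifnot(inherits(map, "dose_map_polar"))
  sk <- as.numeric(sk)
  if (!is.finite(sk) || sk <= 0) stop("sk must be finite and > 0")

  ir0 <- which.min(abs(map$radii_cm - .TG43_R0))
  it0 <- which.min(abs(map$angles_deg - .TG43_THETA0))
  if (abs(map$radii_cm[ir0] - .TG43_R0) > tol_r)
    stop(sprintf("no sampled radius within %g cm of the 1 cm reference (nearest: %g cm)",
                 tol_r, map$radii_cm[ir0]))
  if (abs(map$angles_deg[it0] - .TG43_THETA0) > tol_theta)
    stop(sprintf("no sampled angle within %g deg of the 90 deg reference (nearest: %g deg)",
                 tol_theta, map$angles_deg[it0]))
  r0 <- map$radii_cm[ir0]
  D0 <- map$dose_rate[ir0, it0]
  if (D0 <= 0) stop("zero dose rate at the reference point; cannot normalize")

  lambda <- D0 / sk
  Dtrans <- map$dose_rate[, it0]
  if (any(Dtrans <= 0))
    stop("zero dose rate on the transverse axis; cannot form g(r)")
  g <- (Dtrans * geometry_point(r0)) / (D0 * geometry_point(map$radii_cm))
  if (!is.null(smooth_g_order)) {
    order <- as.integer(smooth_g_order)
    if (order < 1L || order >= length(map$radii_cm) - 1L)
      stop("smooth_g_order must be >= 1 and leave residual degrees of freedom")
    # inverse-square-corrected transverse profile is Sk*Lambda*g(r)
    r <- map$radii_cm
    fit <- stats::lm(I(Dtrans * r^2) ~ stats::poly(r, order, raw = TRUE))
    pred <- as.numeric(stats::fitted(fit))
    if (any(pred <= 0))
      stop("polynomial fit of g(r) is non-positive at some sampled radii; lower smooth_g_order")
    g <- pred / pred[ir0]
  }

  # anisotropy: geometry cancels within a radius; keep angles strictly
  # inside (0, 180) as the table type requires
  keep <- map$angles_deg > 0 & map$angles_deg < 180
  Fm <- map$dose_rate[, keep, drop = FALSE] / Dtrans

  source_model(
    dose_rate_constant = lambda,
    air_kerma_strength = sk,
    radial_table = radial_dose_table(map$radii_cm, g,
                                     reference_radius_cm = r0),
    anisotropy_table = anisotropy_table(map$radii_cm,
                                        map$angles_deg[keep], Fm),
    label = label)
}

#' Air-kerma strength from kerma-rate samples
#'
#' The air-kerma strength Sk is the in-air kerma rate times distance
#' squared; for an ideal point source the product is distance-independent.
#' This estimator forms kerma(d) * d^2 at every sample inside `fit_range`
#' and averages them with equal weight, returning the per-sample products
#' as well so distance-independence can be checked. The default range
#' 5-100 cm avoids the near field (finite source size) and the far field
#' (poor sampling statistics).
#'
#' @param samples A [kerma_samples()].
#' @param fit_range Length-2 numeric, cm interval of distances to use.
#' @return A list of class `sk_estimate`: `sk` (U, taking kerma in
#'   uGy m^2 h^-1 cm^-2-free units, i.e. the product's natural unit),
#'   `per_sample` (data frame of distance and product), `fit_range`.
#' @export
air_kerma_strength <- function(samples, fit_range = c(5, 100)) {
  stopifnot(inherits(samples, "kerma_samples"))
  fit_range <- sort(as.numeric(fit_range))
  if (length(fit_range) != 2L || any(!is.finite(fit_range)))
    stop("fit_range must be a finite length-2 interval in cm")
  inside <- samples$distances_cm >= fit_range[1L] &
    samples$distances_cm <= fit_range[2L]
  if (!any(inside))
    stop(sprintf("no kerma samples inside fit range [%g, %g] cm",
                 fit_range[1L], fit_range[2L]))
  d <- samples$distances_cm[inside]
  prod <- samples$kerma_rate[inside] * d^2
  structure(list(sk = mean(prod),
                 per_sample = data.frame(distance_cm = d, kerma_d2 = prod),
                 fit_range = fit_range),
            class = "sk_estimate")
}

#' @export
print.sk_estimate <- function(x, ...) {
  cat(sprintf("Sk = %.6g (mean of kerma*d^2 over %d samples in [%g, %g] cm)\n",
              x$sk, nrow(x$per_sample), x$fit_range[1L], x$fit_range[2L]))
  spread <- range(x$per_sample$kerma_d2)
  cat(sprintf("  per-sample range: [%.6g, %.6g]\n", spread[1L], spread[2L]))
  invisible(x)
}

#' Polar dose-rate map around a single source
#'
#' Sampled dose rates D(r, theta) on a polar grid centered on one source,
#' the input to [extract_parameters()].
#'
#' @param radii_cm Strictly increasing positive distances, cm.
#' @param angles_deg Strictly increasing angles in \[0, 180\] degrees.
#' @param dose_rate Matrix of non-negative dose rates, dimensions
#'   `(n_radii, n_angles)`.
#' @return An object of class `dose_map_polar`.
#' @export
dose_map_polar <- function(radii_cm, angles_deg, dose_rate) {
  radii_cm <- as.numeric(radii_cm)
  angles_deg <- as.numeric(angles_deg)
  dose_rate <- as.matrix(dose_rate)
  storage.mode(dose_rate) <- "double"
  if (any(!is.finite(radii_cm)) || any(radii_cm <= 0) || any(diff(radii_cm) <= 0))
    stop("radii must be > 0 and strictly increasing")
  if (any(!is.finite(angles_deg)) || any(angles_deg < 0) ||
      any(angles_deg > 180) || any(diff(angles_deg) <= 0))
    stop("angles must be strictly increasing within [0, 180]")
  if (!identical(dim(dose_rate), c(length(radii_cm), length(angles_deg))))
    stop("dose_rate must have dimensions (n_radii, n_angles)")
  if (any(!is.finite(dose_rate)) || any(dose_rate < 0))
    stop("dose rates must be finite and >= 0")
  structure(list(radii_cm = radii_cm, angles_deg = angles_deg,
                 dose_rate = dose_rate),
            class = "dose_map_polar")
}

#' In-air kerma-rate samples versus distance
#'
#' @param distances_cm Positive sample distances, cm.
#' @param kerma_rate Non-negative air-kerma rates, one per distance.
#' @return An object of class `kerma_samples`.
#' @export
kerma_samples <- function(distances_cm, kerma_rate) {
  distances_cm <- as.numeric(distances_cm)
  kerma_rate <- as.numeric(kerma_rate)
  if (length(distances_cm) != length(kerma_rate) || length(distances_cm) < 1L)
    stop("distances and kerma rates must be non-empty and of equal length")
  if (any(!is.finite(distances_cm)) || any(distances_cm <= 0))
    stop("distances must be finite and > 0")
  if (any(!is.finite(kerma_rate)) || any(kerma_rate < 0))
    stop("kerma rates must be finite and >= 0")
  structure(list(distances_cm = distances_cm, kerma_rate = kerma_rate),
            class = "kerma_samples")
}

#' Read a polar dose map file
#'
#' Delimited text in the same dialect family as the anisotropy table: lines
#' starting with `#` are comments, the first data row lists the angles in
#' degrees, and each remaining row starts with the radius in cm followed by
#' the dose rates at each angle.
#'
#' @param path File path.
#' @return A [dose_map_polar()].
#' @export
read_dose_map <- function(path) {
  if (!file.exists(path)) stop("dose map file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rows <- .parse_numeric_rows(lines, path, "dose map")
  if (length(rows) < 2L) stop("dose map file ", path, ": need angle row plus data rows")
  angles <- rows[[1L]]
  body <- do.call(rbind, rows[-1L])
  if (ncol(body) != length(angles) + 1L)
    stop("dose map file ", path, ": rows must have 1 + n_angles values")
  dose_map_polar(body[, 1L], angles, body[, -1L, drop = FALSE])
}

#' Write a polar dose map file
#'
#' @param map A [dose_map_polar()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_map <- function(map, path) {
  stopifnot(inherits(map, "dose_map_polar"))
  num <- function(x) sprintf("%.17g", x)
  out <- c("# polar dose map: first row angles (deg), first column radii (cm)",
           paste(num(map$angles_deg), collapse = " "))
  for (i in seq_along(map$radii_cm))
    out <- c(out, paste(num(c(map$radii_cm[i], map$dose_rate[i, ])),
                        collapse = " "))
  writeLines(out, path)
  invisible(path)
}
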
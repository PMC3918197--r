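#' Radial dose function table
#'
#' Container for a tabulated TG-43U1 radial dose function g(r): the
#' transverse-axis dose fall-off beyond inverse square, normalized to 1 at
#' the reference radius r0 (1 cm by convention).
#'
#' @param radii_cm Strictly increasing positive distances from the source
#'   center, in cm.
#' @param g_values Dimensionless g(r) values, one per radius, all positive.
#' @param reference_radius_cm Reference radius r0 in cm (default 1).
#'
#' @return An object of class `radial_dose_table`.
#' @examples
#' g <- radial_dose_table(c(1, 2, 3), c(1.0, 0.9, 0.8))
#' eval_g(g, 2.5)
#' @export
radial_dose_table <- function(radii_cm, g_values, reference_radius_cm = 1.0) {
  radii_cm <- as.numeric(radii_cm)
  g_values <- as.numeric(g_values)
  if (length(radii_cm) < 1L || length(radii_cm) != length(g_values))
    stop("radii_cm and g_values must be non-empty and of equal length")
  if (any(!is.finite(radii_cm)) || any(!is.finite(g_values)))
    stop("radial dose table contains non-finite entries")
  if (any(radii_cm <= 0))
    stop("all radii must be > 0")
  if (any(diff(radii_cm) <= 0))
    stop("radii must be strictly increasing")
  if (any(g_values <= 0))
    stop("all g(r) values must be > 0")
  g0 <- .interp1(radii_cm, g_values, reference_radius_cm)
  if (abs(g0 - 1.0) > 1e-9)
    stop(sprintf("g(r0 = %g cm) = %.12g; radial dose function must be normalized to 1 at r0",
                 reference_radius_cm, g0))
  structure(
    list(radii_cm = radii_cm, g_values = g_values,
         reference_radius_cm = reference_radius_cm),
    class = "radial_dose_table")
}

#' 2D anisotropy function table
#'
#' Container for a tabulated TG-43U1 2D anisotropy function F(r, theta):
#' angular dose variation relative to the transverse axis, normalized to 1
#' at theta0 = 90 degrees. No mirror symmetry about 90 degrees is assumed;
#' a pellet inside an applicator sees different material toward the tip and
#' the base, so the table is stored exactly as given.
#'
#' @param radii_cm Strictly increasing positive distances, in cm.
#' @param angles_deg Strictly increasing polar angles in (0, 180) degrees.
#' @param F_values Matrix of dimensionless F values with dimensions
#'   `length(radii_cm) x length(angles_deg)`.
#'
#' @return An object of class `anisotropy_table`.
#' @export
anisotropy_table <- function(radii_cm, angles_deg, F_values) {
  radii_cm <- as.numeric(radii_cm)
  angles_deg <- as.numeric(angles_deg)
  F_values <- as.matrix(F_values)
  storage.mode(F_values) <- "double"
  if (any(!is.finite(radii_cm)) || any(radii_cm <= 0) || any(diff(radii_cm) <= 0))
    stop("radii must be finite, > 0 and strictly increasing")
  if (any(!is.finite(angles_deg)) || any(angles_deg <= 0) || any(angles_deg >= 180) ||
      any(diff(angles_deg) <= 0))
    stop("angles must be strictly increasing and inside (0, 180) degrees")
  if (!identical(dim(F_values), c(length(radii_cm), length(angles_deg))))
    stop("F_values must have dimensions (n_radii, n_angles)")
  if (any(!is.finite(F_values)) || any(F_values <= 0))
    stop("all F values must be finite and > 0")
  i90 <- which(angles_deg == 90)
  if (length(i90) == 1L && any(abs(F_values[, i90] - 1.0) > 1e-9)) {
    bad <- which(abs(F_values[, i90] - 1.0) > 1e-9)[1L]
    stop(sprintf("F(r = %g cm, 90 deg) = %.12g; anisotropy function must be normalized to 1 on the transverse axis",
                 radii_cm[bad], F_values[bad, i90]))
  }
  dimnames(F_values) <- list(format(radii_cm), format(angles_deg))
  structure(
    list(radii_cm = radii_cm, angles_deg = angles_deg, F_values = F_values),
    class = "anisotropy_table")
}

# linear interpolation with clamp-to-edge, no warning (internal workhorse)
.interp1 <- function(x, y, xout) {
  if (length(x) == 1L) return(rep(y, length(xout)))
  stats::approx(x, y, xout = xout, method = "linear", rule = 2, ties = "ordered")$y
}

#' Evaluate the radial dose function
#'
#' Linear interpolation between tabulated nodes; node values are reproduced
#' exactly. Outside the tabulated range the value is clamped to the nearest
#' end node and a warning is emitted, since published g(r) tables for LDR
#' sources are coarse and polynomial extrapolation beyond them is unsafe.
#'
#' @param table A [radial_dose_table()].
#' @param r Distance(s) from the source center in cm; must be > 0.
#' @return g(r), dimensionless, same length as `r`.
#' @export
eval_g <- function(table, r) {
  stopifnot(inherits(table, "radial_dose_table"))
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("r must be finite and > 0")
  rng <- range(table$radii_cm)
  if (any(r < rng[1L] | r > rng[2L]))
    warning(sprintf("g(r) evaluated outside tabulated range [%g, %g] cm; clamped to end value",
                    rng[1L], rng[2L]))
  .interp1(table$radii_cm, table$g_values, r)
}

#' Evaluate the 2D anisotropy function
#'
#' Bilinear interpolation (linear in r and in theta) inside the tabulated
#' grid; grid nodes are reproduced exactly. Outside the grid the value is
#' clamped to the nearest edge and a warning is emitted. Published pellet
#' tables typically stop at 15 and 165 degrees; points nearer the poles take
#' the edge value.
#'
#' @param table An [anisotropy_table()].
#' @param r Distance(s) in cm, > 0.
#' @param theta Polar angle(s) in degrees, in \[0, 180\].
#' @return F(r, theta), dimensionless. `r` and `theta` are recycled to a
#'   common length.
#' @export
eval_F <- function(table, r, theta) {
  stopifnot(inherits(table, "anisotropy_table"))
  r <- as.numeric(r); theta <- as.numeric(theta)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("r must be finite and > 0")
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 180))
    stop("theta must be within [0, 180] degrees")
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)

  rr <- table$radii_cm; aa <- table$angles_deg
  if (any(r < rr[1L] | r > rr[length(rr)]))
    warning(sprintf("F(r, theta) evaluated outside tabulated radii [%g, %g] cm; clamped",
                    rr[1L], rr[length(rr)]))
  if (any(theta < aa[1L] | theta > aa[length(aa)]))
    warning(sprintf("F(r, theta) evaluated outside tabulated angles [%g, %g] deg; clamped",
                    aa[1L], aa[length(aa)]))
  rc <- pmin(pmax(r, rr[1L]), rr[length(rr)])
  tc <- pmin(pmax(theta, aa[1L]), aa[length(aa)])

  # bracketing indices (degenerate single-node axes collapse to weight 0)
  ir <- if (length(rr) > 1L) pmin(pmax(findInterval(rc, rr), 1L), length(rr) - 1L) else 1L
  ia <- if (length(aa) > 1L) pmin(pmax(findInterval(tc, aa), 1L), length(aa) - 1L) else 1L
  wr <- if (length(rr) > 1L) (rc - rr[ir]) / (rr[ir + 1L] - rr[ir]) else 0
  wa <- if (length(aa) > 1L) (tc - aa[ia]) / (aa[ia + 1L] - aa[ia]) else 0
  ir2 <- if (length(rr) > 1L) ir + 1L else ir
  ia2 <- if (length(aa) > 1L) ia + 1L else ia
  Fm <- table$F_values
  (1 - wr) * (1 - wa) * Fm[cbind(ir,  ia)] +
    wr * (1 - wa) * Fm[cbind(ir2, ia)] +
    (1 - wr) * wa * Fm[cbind(ir,  ia2)] +
    wr * wa * Fm[cbind(ir2, ia2)]
}

#' @export
print.radial_dose_table <- function(x, ...) {
  cat(sprintf("Radial dose function g(r): %d nodes, r in [%g, %g] cm (r0 = %g cm)\n",
              length(x$radii_cm), min(x$radii_cm), max(x$radii_cm),
              x$reference_radius_cm))
  print(data.frame(r_cm = x$radii_cm, g = x$g_values), row.names = FALSE)
  invisible(x)
}

#' @export
print.anisotropy_table <- function(x, ...) {
  cat(sprintf("2D anisotropy function F(r, theta): %d radii x %d angles\n",
              length(x$radii_cm), length(x$angles_deg)))
  print(x$F_values)
  invisible(x)
}
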
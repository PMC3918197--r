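#' Dose-rate grid
#'
#' Cartesian scalar dose-rate field with geometry metadata. Voxels inside a
#' pellet (or otherwise unevaluable) are masked with `NA` rather than
#' extrapolated. Axes with a single sample give planar (2D) or linear (1D)
#' grids; isodose extraction requires a planar grid.
#'
#' @param x,y,z Voxel-center coordinate vectors, cm (strictly increasing;
#'   length 1 allowed).
#' @param values Array of dose rates with dim `c(length(x), length(y),
#'   length(z))`; `NA` marks masked voxels.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(x, y, z, values) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  for (ax in list(x, y, z))
    if (length(ax) < 1L || any(!is.finite(ax)) || any(diff(ax) <= 0))
      stop("grid axes must be finite, non-empty and strictly increasing")
  values <- array(as.numeric(values), dim = c(length(x), length(y), length(z)))
  if (any(!is.na(values) & !is.finite(values)))
    stop("unmasked grid values must be finite")
  structure(list(x = x, y = y, z = z, values = values,
                 mask = is.na(values)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("Dose grid: %d x %d x %d voxels, %d masked\n",
              length(x$x), length(x$y), length(x$z), sum(x$mask)))
  sp <- vapply(list(x$x, x$y, x$z),
               function(a) if (length(a) > 1L) a[2L] - a[1L] else NA_real_,
               numeric(1))
  cat(sprintf("  origin (%g, %g, %g) cm, spacing (%s) cm\n",
              x$x[1L], x$y[1L], x$z[1L],
              paste(format(sp), collapse = ", ")))
  invisible(x)
}

#' TG-43U1 pellet-train dose engine
#'
#' Wraps a configuration and source library into an evaluator suitable for
#' [compute_grid()]: a function taking an `n x 3` matrix of points (cm)
#' and returning dose rates in cGy/h, `NA` where a point is masked.
#'
#' @param config A [train_configuration()].
#' @param library A [source_library()] or single [source_model()].
#' @return A function `(points) -> dose rates`.
#' @export
tg43_train_engine <- function(config, library) {
  if (inherits(library, "source_model")) library <- source_library(library)
  stopifnot(inherits(config, "train_configuration"),
            inherits(library, "source_library"))
  force(config); force(library)
  function(points) {
    if (!is.matrix(points)) points <- matrix(points, ncol = 3L, byrow = TRUE)
    train_dose(config, library, points)
  }
}

#' Legacy pellet-train dose engine
#'
#' Evaluator counterpart of [tg43_train_engine()] for the legacy
#' point-source formalism.
#'
#' @param config A [train_configuration()].
#' @param params A [legacy_parameters()].
#' @return A function `(points) -> dose rates`.
#' @export
legacy_train_engine <- function(config, params) {
  stopifnot(inherits(config, "train_configuration"),
            inherits(params, "legacy_parameters"))
  force(config); force(params)
  function(points) {
    if (!is.matrix(points)) points <- matrix(points, ncol = 3L, byrow = TRUE)
    legacy_train_dose(config, params, points)
  }
}

#' Evaluate an engine on a box region
#'
#' Samples a dose engine at every voxel center of a regular grid spanning
#' the given box. A degenerate interval (`min == max`) produces a single
#' sample along that axis, which is how longitudinal-plane (y = const)
#' grids are built. The default 0.125 cm spacing matches the fine scoring
#' lattice resolution typical of pellet dosimetry.
#'
#' @param engine An evaluator from [tg43_train_engine()] or
#'   [legacy_train_engine()] (any function mapping an `n x 3` point matrix
#'   to dose rates).
#' @param xlim,ylim,zlim Length-2 intervals, cm.
#' @param spacing Voxel spacing, cm (scalar or per-axis length 3).
#' @return A [dose_grid()].
#' @export
compute_grid <- function(engine, xlim, ylim, zlim, spacing = 0.125) {
  stopifnot(is.function(engine))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be > 0")
  ax <- function(lim, sp) {
    lim <- sort(as.numeric(lim))
    if (lim[1L] == lim[2L]) lim[1L] else seq(lim[1L], lim[2L], by = sp)
  }
  x <- ax(xlim, spacing[1L]); y <- ax(ylim, spacing[2L]); z <- ax(zlim, spacing[3L])
  pts <- as.matrix(expand.grid(x = x, y = y, z = z, KEEP.OUT.ATTRS = FALSE))
  vals <- suppressWarnings(engine(pts))
  dose_grid(x, y, z, array(vals, dim = c(length(x), length(y), length(z))))
}

#' Voxel-wise percent difference of two congruent grids
#'
#' Computes 100 * (b - a) / a per voxel, the conventional comparison map
#' normalized to the reference engine `a`. Voxels masked in either grid,
#' or where `a` is zero, are masked in the result. Grids must be congruent
#' (identical axes); no interpolation is performed.
#'
#' @param a Reference [dose_grid()] (denominator).
#' @param b Comparison [dose_grid()].
#' @return A [dose_grid()] of percent differences.
#' @export
percent_difference <- function(a, b) {
  stopifnot(inherits(a, "dose_grid"), inherits(b, "dose_grid"))
  if (!isTRUE(all.equal(a$x, b$x, tolerance = 0)) ||
      !isTRUE(all.equal(a$y, b$y, tolerance = 0)) ||
      !isTRUE(all.equal(a$z, b$z, tolerance = 0)))
    stop("grids are not congruent (origin/spacing/shape differ)")
  pd <- 100 * (b$values - a$values) / a$values
  pd[a$mask | b$mask | a$values == 0] <- NA_real_
  dose_grid(a$x, a$y, a$z, pd)
}

# identify the in-plane axes of a planar grid
.plane_axes <- function(grid) {
  n <- c(length(grid$x), length(grid$y), length(grid$z))
  flat <- which(n == 1L)
  if (length(flat) != 1L)
    stop("grid is not planar: exactly one axis must have a single sample")
  setdiff(1:3, flat)
}

#' Isodose contour extraction
#'
#' Extracts equal-dose-rate contours from a planar grid by marching
#' squares with linear edge interpolation (via [grDevices::contourLines()]).
#' Polylines are closed or terminate on the grid boundary; vertex order is
#' deterministic. Levels outside the grid's value range yield no polylines
#' (not an error). Masked voxels are excluded from contouring.
#'
#' @param grid A planar [dose_grid()].
#' @param levels Numeric dose-rate levels, cGy/h.
#' @return A list with one element per level: a list of polylines, each a
#'   data frame with the two in-plane coordinates (named after the axes).
#' @export
isodose_contours <- function(grid, levels) {
  stopifnot(inherits(grid, "dose_grid"))
  levels <- as.numeric(levels)
  if (any(!is.finite(levels))) stop("levels must be finite")
  ij <- .plane_axes(grid)
  axes <- list(grid$x, grid$y, grid$z)
  u <- axes[[ij[1L]]]; v <- axes[[ij[2L]]]
  m <- matrix(grid$values, length(u), length(v))
  nm <- c("x", "y", "z")[ij]
  out <- vector("list", length(levels))
  names(out) <- format(levels)
  for (k in seq_along(levels)) {
    cl <- grDevices::contourLines(u, v, m, levels = levels[k])
    out[[k]] <- lapply(cl, function(seg) {
      df <- data.frame(seg$x, seg$y)
      names(df) <- nm
      df
    })
  }
  out
}

#' Write contours to a delimited polyline file
#'
#' One row per vertex with columns `level`, `polyline` (segment index
#' within its level) and the two in-plane coordinates; tab-delimited with
#' a header row.
#'
#' @param contours Output of [isodose_contours()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  rows <- list()
  for (k in seq_along(contours)) {
    polys <- contours[[k]]
    for (s in seq_along(polys)) {
      df <- polys[[s]]
      rows[[length(rows) + 1L]] <-
        cbind(level = as.numeric(names(contours)[k]), polyline = s, df)
    }
  }
  if (length(rows) == 0L) {
    writeLines("level\tpolyline", path)
    return(invisible(path))
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dose profile along the applicator axis beyond the tip
#'
#' Samples an engine along a line parallel to the applicator axis,
#' starting at the applicator tip and extending away from the train (the
#' distal direction). The tip plane is taken at the first slot center
#' minus one pellet radius (0.125 cm), i.e. the distal surface of the
#' tip-most pellet. This is the region where isotropic legacy engines
#' overestimate dose most strongly, since every pellet is seen end-on.
#'
#' @param engine Evaluator from [tg43_train_engine()] or
#'   [legacy_train_engine()].
#' @param config The [train_configuration()] defining tip and axis.
#' @param distances_cm Distances beyond the tip to sample, cm (> 0).
#' @param radial_offset_cm Perpendicular offset of the sampling line from
#'   the axis, cm (default 0 = on-axis).
#' @return A data frame with columns `distance_cm` and `dose_cGy_h`.
#' @export
axial_profile <- function(engine, config, distances_cm = seq(0.25, 5, by = 0.25),
                          radial_offset_cm = 0) {
  stopifnot(is.function(engine), inherits(config, "train_configuration"))
  distances_cm <- as.numeric(distances_cm)
  if (any(!is.finite(distances_cm)) || any(distances_cm <= 0))
    stop("distances beyond the tip must be > 0")
  tip <- (config$tip_position_cm - .PELLET_RADIUS_CM) * config$axis
  perp <- .any_perpendicular(config$axis)
  pts <- t(vapply(distances_cm,
                  function(s) tip - s * config$axis + radial_offset_cm * perp,
                  numeric(3)))
  dose <- engine(pts)
  if (all(is.na(dose))) stop("profile line is fully masked")
  data.frame(distance_cm = distances_cm, dose_cGy_h = dose)
}

# unit vector orthogonal to u (deterministic choice)
.any_perpendicular <- function(u) {
  b <- if (abs(u[1L]) <= abs(u[2L]) && abs(u[1L]) <= abs(u[3L])) c(1, 0, 0)
       else if (abs(u[2L]) <= abs(u[3L])) c(0, 1, 0) else c(0, 0, 1)
  v <- c(u[2L] * b[3L] - u[3L] * b[2L],
         u[3L] * b[1L] - u[1L] * b[3L],
         u[1L] * b[2L] - u[2L] * b[1L])
  v / sqrt(sum(v^2))
}

#' Write a planar dose grid as a delimited matrix with sidecar header
#'
#' The matrix rows follow the first in-plane axis; a `<path>.hdr` sidecar
#' records origin, spacing and shape. Non-planar grids are written in long
#' format (x, y, z, value).
#'
#' @param grid A [dose_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  sp <- vapply(list(grid$x, grid$y, grid$z),
               function(a) if (length(a) > 1L) a[2L] - a[1L] else 0,
               numeric(1))
  hdr <- c(sprintf("origin_cm = %.17g %.17g %.17g",
                   grid$x[1L], grid$y[1L], grid$z[1L]),
           sprintf("spacing_cm = %.17g %.17g %.17g", sp[1L], sp[2L], sp[3L]),
           sprintf("shape = %d %d %d",
                   length(grid$x), length(grid$y), length(grid$z)))
  writeLines(hdr, paste0(path, ".hdr"))
  n <- c(length(grid$x), length(grid$y), length(grid$z))
  if (sum(n == 1L) == 1L) {
    ij <- .plane_axes(grid)
    axes <- list(grid$x, grid$y, grid$z)
    m <- matrix(grid$values, n[ij[1L]], n[ij[2L]])
    utils::write.table(m, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    long <- cbind(as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z,
                                        KEEP.OUT.ATTRS = FALSE)),
                  value = as.vector(grid$values))
    utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Plot isodose contours
#'
#' Draws isodose curves of one or two planar grids in a longitudinal
#' plane, in the style of engine-comparison figures (solid for the first
#' grid, dashed for the second).
#'
#' @param grid A planar [dose_grid()].
#' @param levels Dose-rate levels, cGy/h.
#' @param grid2 Optional second grid (same plane) to overlay.
#' @param main Plot title.
#' @return Invisibly, the contours of `grid`.
#' @export
plot_isodose <- function(grid, levels, grid2 = NULL, main = "Isodose curves") {
  ij <- .plane_axes(grid)
  axes <- list(grid$x, grid$y, grid$z)
  nm <- c("x", "y", "z")[ij]
  c1 <- isodose_contours(grid, levels)
  graphics::plot(NA, xlim = range(axes[[ij[1L]]]), ylim = range(axes[[ij[2L]]]),
                 xlab = paste0(nm[1L], " (cm)"), ylab = paste0(nm[2L], " (cm)"),
                 main = main, asp = 1)
  cols <- grDevices::hcl.colors(max(length(levels), 2L), "Dark 3")
  for (k in seq_along(c1))
    for (seg in c1[[k]])
      graphics::lines(seg[[1L]], seg[[2L]], col = cols[k], lty = 1)
  if (!is.null(grid2)) {
    c2 <- isodose_contours(grid2, levels)
    for (k in seq_along(c2))
      for (seg in c2[[k]])
        graphics::lines(seg[[1L]], seg[[2L]], col = cols[k], lty = 2)
  }
  invisible(c1)
}
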
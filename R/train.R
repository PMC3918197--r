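# Selectron pellet geometry: 0.75 mm active core + 0.5 mm steel shell
# => 1.25 mm outer radius, 2.5 mm diameter; touching pellets pitch 0.25 cm
.PELLET_RADIUS_CM <- 0.125
.DEFAULT_PITCH_CM <- 0.25

#' Pellet-train configuration
#'
#' Describes the ordered train of spherical pellets inside a straight
#' cylindrical applicator: total slot count, which slots hold active
#' sources versus inactive spacers, center-to-center pitch, the axial
#' coordinate of the first (tip-most) slot center and the longitudinal
#' axis direction. Slot 1 is nearest the applicator tip; slot index grows
#' toward the base along `axis`.
#'
#' The polar-angle convention for anisotropy lookups is configurable via
#' `theta_zero`: `"tip"` (default) takes theta = 0 to point from a pellet
#' toward the applicator tip, `"base"` takes it toward the base.
#'
#' @param active_flags Logical vector, one per slot; `TRUE` = active pellet.
#'   An active-pattern string such as `"AAAAAIIAAA"` (A = active,
#'   I = inactive) is also accepted.
#' @param pellet_pitch_cm Center-to-center slot spacing, cm (default 0.25,
#'   touching 2.5 mm pellets).
#' @param tip_position_cm Axial coordinate of the first slot center, cm.
#' @param axis Length-3 direction of the applicator's longitudinal axis,
#'   pointing from tip toward base; normalized internally. Default +z.
#' @param theta_zero `"tip"` or `"base"`; see above.
#' @return An object of class `train_configuration`.
#' @examples
#' train_configuration("AAAAAIIAAA")
#' @export
train_configuration <- function(active_flags,
                                pellet_pitch_cm = .DEFAULT_PITCH_CM,
                                tip_position_cm = 0,
                                axis = c(0, 0, 1),
                                theta_zero = c("tip", "base")) {
  if (is.character(active_flags) && length(active_flags) == 1L) {
    chars <- strsplit(toupper(active_flags), "")[[1L]]
    if (!all(chars %in% c("A", "I")))
      stop("active-pattern string may contain only 'A' (active) and 'I' (inactive)")
    active_flags <- chars == "A"
  }
  active_flags <- as.logical(active_flags)
  if (length(active_flags) < 1L || anyNA(active_flags))
    stop("active_flags must be a non-empty logical vector")
  pellet_pitch_cm <- as.numeric(pellet_pitch_cm)
  if (!is.finite(pellet_pitch_cm) || pellet_pitch_cm <= 0)
    stop("pellet_pitch_cm must be > 0")
  axis <- as.numeric(axis)
  if (length(axis) != 3L || any(!is.finite(axis)) || sum(axis^2) == 0)
    stop("axis must be a finite non-zero length-3 vector")
  axis <- axis / sqrt(sum(axis^2))
  theta_zero <- match.arg(theta_zero)
  structure(
    list(n_slots = length(active_flags),
         active_flags = active_flags,
         pellet_pitch_cm = pellet_pitch_cm,
         tip_position_cm = as.numeric(tip_position_cm),
         axis = axis,
         theta_zero = theta_zero),
    class = "train_configuration")
}

#' @export
print.train_configuration <- function(x, ...) {
  cat(sprintf("Pellet train: %d slots (%d active), pitch %g cm, tip at %g cm, theta=0 toward %s\n",
              x$n_slots, sum(x$active_flags), x$pellet_pitch_cm,
              x$tip_position_cm, x$theta_zero))
  cat("  pattern: ", paste(ifelse(x$active_flags, "A", "I"), collapse = ""),
      "\n", sep = "")
  invisible(x)
}

#' Slot center coordinates
#'
#' @param config A [train_configuration()].
#' @return An `n_slots x 3` matrix of pellet-center coordinates (cm) in the
#'   applicator frame; row i is slot i, counted from the tip.
#' @export
pellet_centers <- function(config) {
  stopifnot(inherits(config, "train_configuration"))
  s <- config$tip_position_cm +
    (seq_len(config$n_slots) - 1L) * config$pellet_pitch_cm
  outer(s, config$axis)
}

#' Local polar coordinates of a point relative to a pellet
#'
#' @param pellet_center Length-3 pellet center, cm.
#' @param q Length-3 evaluation point, cm.
#' @param axis Length-3 reference direction for theta = 0; normalized
#'   internally.
#' @return `c(r, theta)`: Euclidean distance in cm and the angle in degrees
#'   (in \[0, 180\]) between `axis` and the vector from the pellet to `q`.
#' @export
local_polar <- function(pellet_center, q, axis = c(0, 0, 1)) {
  pellet_center <- as.numeric(pellet_center)
  q <- as.numeric(q)
  axis <- as.numeric(axis)
  stopifnot(length(pellet_center) == 3L, length(q) == 3L, length(axis) == 3L)
  if (any(!is.finite(q))) stop("evaluation point must be finite")
  v <- q - pellet_center
  r <- sqrt(sum(v^2))
  if (r == 0) stop("evaluation point coincides with the pellet center")
  u <- axis / sqrt(sum(axis^2))
  cosang <- sum(v * u) / r
  theta <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  c(r = r, theta = theta)
}

# per-pellet (r_i, theta_i) for all active slots; theta measured from the
# configured theta-zero direction (tip => -axis, base => +axis)
.train_polar <- function(config, q) {
  centers <- pellet_centers(config)[config$active_flags, , drop = FALSE]
  u <- if (config$theta_zero == "tip") -config$axis else config$axis
  dv <- matrix(q, nrow(centers), 3L, byrow = TRUE) - centers
  r <- sqrt(rowSums(dv^2))
  cosang <- (dv %*% u) / pmax(r, .Machine$double.xmin)
  theta <- acos(pmin(pmax(as.numeric(cosang), -1), 1)) * 180 / pi
  list(r = r, theta = theta,
       slots = which(config$active_flags))
}

#' Pellet-train dose rate by TG-43U1 superposition
#'
#' Sums the single-source TG-43U1 dose rate of every active pellet at a
#' point: each slot's contribution uses the parameter set derived for that
#' slot (falling back to the library default). Inactive spacer pellets
#' contribute no dose; their shielding is already folded into the
#' per-position g and F tables, which is how applicator and inter-pellet
#' attenuation enter a superposition engine.
#'
#' @param config A [train_configuration()] with at least one active slot.
#' @param library A [source_library()] (a bare [source_model()] is promoted
#'   to a single-model library).
#' @param q Length-3 evaluation point in cm, or an `n x 3` matrix of points.
#' @return Dose rate(s) in cGy/h. Points closer than the pellet outer
#'   radius (0.125 cm) to an active pellet center raise an error for a
#'   single point; for a matrix of points they return `NA` (masked).
#' @export
train_dose <- function(config, library, q) {
  stopifnot(inherits(config, "train_configuration"))
  if (inherits(library, "source_model")) library <- source_library(library)
  stopifnot(inherits(library, "source_library"))
  if (!any(config$active_flags))
    stop("configuration has no active pellets")
  .dedup_warnings({
    if (is.matrix(q)) {
      stopifnot(ncol(q) == 3L)
      vapply(seq_len(nrow(q)),
             function(i) .train_dose_point(config, library, q[i, ],
                                           masked_na = TRUE),
             numeric(1))
    } else {
      .train_dose_point(config, library, as.numeric(q), masked_na = FALSE)
    }
  })
}

# evaluate expr, re-emitting each distinct warning once (a 48-pellet train
# would otherwise repeat the same clamp warning per pellet)
.dedup_warnings <- function(expr) {
  msgs <- character()
  out <- withCallingHandlers(expr, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  for (m in unique(msgs)) warning(m, call. = FALSE)
  out
}

.train_dose_point <- function(config, library, q, masked_na = FALSE) {
  stopifnot(length(q) == 3L)
  if (any(!is.finite(q))) stop("evaluation point must be finite")
  pol <- .train_polar(config, q)
  if (any(pol$r < .PELLET_RADIUS_CM)) {
    if (masked_na) return(NA_real_)
    stop(sprintf("point (%g, %g, %g) lies inside an active pellet (masked)",
                 q[1L], q[2L], q[3L]))
  }
  total <- 0
  for (k in seq_along(pol$slots)) {
    m <- model_for_slot(library, pol$slots[k])
    total <- total + dose_rate(m, pol$r[k], pol$theta[k])
  }
  total
}

#' Read a pellet-train configuration file
#'
#' YAML with keys `pattern` (active-pattern string, A = active,
#' I = inactive), and optional `pitch_cm`, `tip_position_cm`, `axis`
#' (length 3) and `theta_zero`.
#'
#' @param path File path.
#' @return A [train_configuration()].
#' @export
read_train_config <- function(path) {
  if (!file.exists(path)) stop("train configuration file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$pattern)) stop("train configuration ", path, ": missing 'pattern'")
  train_configuration(
    active_flags = y$pattern,
    pellet_pitch_cm = if (is.null(y$pitch_cm)) .DEFAULT_PITCH_CM else y$pitch_cm,
    tip_position_cm = if (is.null(y$tip_position_cm)) 0 else y$tip_position_cm,
    axis = if (is.null(y$axis)) c(0, 0, 1) else unlist(y$axis),
    theta_zero = if (is.null(y$theta_zero)) "tip" else y$theta_zero)
}
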
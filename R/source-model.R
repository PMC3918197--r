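#' TG-43U1 parameter set for one source
#'
#' Bundles the dose-rate constant Lambda, air-kerma strength Sk, radial dose
#' table and anisotropy table of a sealed source. For pellet-train modelling
#' the set may carry the slot (`position_index`) it was derived for: the
#' parameters of a pellet depend on its position inside the applicator,
#' because attenuation by the applicator wall and neighbouring pellets is
#' folded into g(r) and F(r, theta).
#'
#' @param dose_rate_constant Lambda, in cGy h^-1 U^-1; must be > 0.
#' @param air_kerma_strength Sk, in U (1 U = 1 uGy m^2 h^-1); must be >= 0.
#' @param radial_table A [radial_dose_table()].
#' @param anisotropy_table An [anisotropy_table()].
#' @param position_index Optional integer slot index the set was derived for.
#' @param label Free-text description.
#'
#' @return An object of class `source_model`.
#' @export
source_model <- function(dose_rate_constant, air_kerma_strength,
                         radial_table, anisotropy_table,
                         position_index = NA_integer_, label = "") {
  stopifnot(inherits(radial_table, "radial_dose_table"),
            inherits(anisotropy_table, "anisotropy_table"))
  dose_rate_constant <- as.numeric(dose_rate_constant)
  air_kerma_strength <- as.numeric(air_kerma_strength)
  if (!is.finite(dose_rate_constant) || dose_rate_constant <= 0)
    stop("dose_rate_constant (Lambda) must be finite and > 0")
  if (!is.finite(air_kerma_strength) || air_kerma_strength < 0)
    stop("air_kerma_strength (Sk) must be finite and >= 0")
  structure(
    list(dose_rate_constant = dose_rate_constant,
         air_kerma_strength = air_kerma_strength,
         radial_table = radial_table,
         anisotropy_table = anisotropy_table,
         position_index = as.integer(position_index),
         label = as.character(label)),
    class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat("TG-43U1 source model")
  if (nzchar(x$label)) cat(": ", x$label, sep = "")
  cat("\n")
  cat(sprintf("  Lambda = %g cGy/h/U, Sk = %g U", x$dose_rate_constant,
              x$air_kerma_strength))
  if (!is.na(x$position_index)) cat(sprintf(", slot %d", x$position_index))
  cat("\n")
  cat(sprintf("  g(r): %d radii in [%g, %g] cm; F(r,theta): %d x %d grid\n",
              length(x$radial_table$radii_cm),
              min(x$radial_table$radii_cm), max(x$radial_table$radii_cm),
              length(x$anisotropy_table$radii_cm),
              length(x$anisotropy_table$angles_deg)))
  invisible(x)
}

#' Per-slot library of source models
#'
#' Maps pellet-train slot indices to the TG-43U1 parameter set derived for
#' that slot, with a default model for slots that have no dedicated entry
#' (published data typically cover only the first slot).
#'
#' @param default_model A [source_model()] used for unmapped slots.
#' @param models Optional list of [source_model()]s; each must carry a
#'   `position_index`, which becomes its key.
#'
#' @return An object of class `source_library`.
#' @export
source_library <- function(default_model, models = list()) {
  stopifnot(inherits(default_model, "source_model"))
  keyed <- list()
  for (m in models) {
    stopifnot(inherits(m, "source_model"))
    if (is.na(m$position_index))
      stop("every per-slot model must carry a position_index")
    keyed[[as.character(m$position_index)]] <- m
  }
  structure(list(models = keyed, default_model = default_model),
            class = "source_library")
}

#' Look up the source model for a slot
#'
#' @param library A [source_library()].
#' @param position_index Integer slot index.
#' @return The slot's dedicated [source_model()] if present, else the
#'   library default.
#' @export
model_for_slot <- function(library, position_index) {
  stopifnot(inherits(library, "source_library"))
  m <- library$models[[as.character(as.integer(position_index))]]
  if (is.null(m)) library$default_model else m
}

#' @export
print.source_library <- function(x, ...) {
  cat(sprintf("Source library: %d per-slot model(s) + default\n",
              length(x$models)))
  invisible(x)
}
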
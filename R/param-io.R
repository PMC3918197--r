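#' Read a TG-43U1 parameter file
#'
#' Parses the sectioned delimited-text dialect used for pellet parameter
#' sets: a `[meta]` section with `lambda`, `sk`, and optional
#' `position_index` / `label` keys, a `[g]` section with two whitespace- or
#' comma-delimited columns (r in cm, g), and an `[F]` section whose first
#' data row lists the angles in degrees and whose remaining rows start with
#' the radius in cm followed by the F values. Lines beginning with `#` are
#' comments. Normalization is validated on load: g(r0) and F(r, 90 deg)
#' must equal 1 within 1e-6 relative (printed tables carry 3-4 digits).
#'
#' @param path Path to the parameter file.
#' @return A [source_model()].
#' @seealso [write_parameter_file()], [cs137_pellet_model()]
#' @export
load_parameter_file <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sec <- .split_sections(lines)
  for (need in c("meta", "g", "f"))
    if (is.null(sec[[need]]))
      stop(sprintf("parameter file %s: missing [%s] section",
                   path, if (need == "f") "F" else need))

  meta <- .parse_keyvals(sec$meta, path)
  if (is.null(meta$lambda) || is.null(meta$sk))
    stop("parameter file ", path, ": [meta] must define lambda and sk")

  gtab <- .parse_numeric_rows(sec$g, path, "[g]")
  if (any(lengths(gtab) != 2L))
    stop("parameter file ", path, ": [g] rows must have exactly 2 columns (r_cm, g)")
  gmat <- do.call(rbind, gtab)
  radial <- .validated_radial(gmat[, 1L], gmat[, 2L], path)

  frows <- .parse_numeric_rows(sec$f, path, "[F]")
  if (length(frows) < 2L)
    stop("parameter file ", path, ": [F] needs an angle row plus at least one radius row")
  angles <- frows[[1L]]
  body <- frows[-1L]
  if (any(lengths(body) != length(angles) + 1L))
    stop("parameter file ", path,
         ": each [F] radius row must have 1 + n_angles values")
  bmat <- do.call(rbind, body)
  aniso <- .validated_aniso(bmat[, 1L], angles, bmat[, -1L, drop = FALSE], path)

  source_model(
    dose_rate_constant = meta$lambda,
    air_kerma_strength = meta$sk,
    radial_table = radial,
    anisotropy_table = aniso,
    position_index = if (is.null(meta$position_index)) NA_integer_
                     else as.integer(meta$position_index),
    label = if (is.null(meta$label)) "" else meta$label)
}

# validate file-level normalization at the looser printed-table tolerance,
# then rescale residual rounding so the strict type invariants hold exactly
.validated_radial <- function(r, g, path) {
  r0 <- 1.0
  if (any(diff(r) <= 0) || any(r <= 0))
    stop("parameter file ", path, ": [g] radii must be positive and strictly increasing (row ",
         which(c(diff(r) <= 0, FALSE))[1L] + 1L, ")")
  g0 <- .interp1(r, g, r0)
  if (abs(g0 - 1.0) > 1e-6)
    stop(sprintf("parameter file %s: g(r0 = 1 cm) = %.8g, expected 1 (normalization violated)",
                 path, g0))
  radial_dose_table(r, g / g0, reference_radius_cm = r0)
}

.validated_aniso <- function(r, angles, Fm, path) {
  if (any(diff(r) <= 0) || any(r <= 0))
    stop("parameter file ", path, ": [F] radii must be positive and strictly increasing")
  if (any(diff(angles) <= 0))
    stop("parameter file ", path, ": [F] angles must be strictly increasing")
  i90 <- which(angles == 90)
  if (length(i90) == 1L) {
    off <- which(abs(Fm[, i90] - 1.0) > 1e-6)
    if (length(off))
      stop(sprintf("parameter file %s: F(r = %g cm, 90 deg) = %.8g, expected 1 (normalization violated)",
                   path, r[off[1L]], Fm[off[1L], i90]))
    Fm <- Fm / Fm[, i90]
  }
  anisotropy_table(r, angles, Fm)
}

#' Write a TG-43U1 parameter file
#'
#' Writes a [source_model()] in the dialect read by
#' [load_parameter_file()], preserving all numeric content to full double
#' precision so that a load/write/load round trip is exact.
#'
#' @param model A [source_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_file <- function(model, path) {
  stopifnot(inherits(model, "source_model"))
  num <- function(x) sprintf("%.17g", x)
  out <- c(
    "# TG-43U1 pellet parameter set",
    "[meta]",
    paste0("lambda = ", num(model$dose_rate_constant)),
    paste0("sk = ", num(model$air_kerma_strength)),
    if (!is.na(model$position_index))
      paste0("position_index = ", model$position_index),
    if (nzchar(model$label)) paste0("label = ", model$label),
    "[g]",
    paste(num(model$radial_table$radii_cm), num(model$radial_table$g_values)),
    "[F]",
    paste(num(model$anisotropy_table$angles_deg), collapse = " "))
  Fm <- model$anisotropy_table$F_values
  for (i in seq_along(model$anisotropy_table$radii_cm))
    out <- c(out, paste(num(c(model$anisotropy_table$radii_cm[i], Fm[i, ])),
                        collapse = " "))
  writeLines(out, path)
  invisible(path)
}

# --- shared section/row parsing helpers ------------------------------------

.split_sections <- function(lines) {
  lines <- sub("\\s+$", "", lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  hdr <- grepl("^\\s*\\[[^]]+\\]\\s*$", lines)
  if (!any(hdr)) return(list())
  idx <- which(hdr)
  names_ <- tolower(gsub("[][ ]", "", lines[idx]))
  out <- list()
  for (k in seq_along(idx)) {
    from <- idx[k] + 1L
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(lines)
    out[[names_[k]]] <- if (from <= to) lines[from:to] else character()
  }
  out
}

.parse_keyvals <- function(lines, path) {
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("parameter file ", path, ": expected 'key = value', got: ", ln)
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(strsplit(val, "[,;[:space:]]+")[[1L]]))
    out[[key]] <- if (key != "label" && !anyNA(num)) num else val
  }
  out
}

.parse_numeric_rows <- function(lines, path, section) {
  lapply(lines, function(ln) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[,;[:space:]]+")[[1L]]))
    if (length(v) == 0L || anyNA(v))
      stop("parameter file ", path, ": non-numeric row in ", section, ": ", ln)
    v
  })
}
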
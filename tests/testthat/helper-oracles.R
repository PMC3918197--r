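# Independent oracles and random-model generators shared across tests.
# The oracles deliberately re-derive every quantity with their own code
# (stats::approx, explicit trigonometry, explicit sums) so they exercise
# none of the package's evaluation paths.

# clamp-to-edge linear interpolation via stats::approx
oracle_g <- function(model, r) {
  tab <- model$radial_table
  stats::approx(tab$radii_cm, tab$g_values, xout = r, rule = 2)$y
}

# bilinear: interpolate each bracketing radius row over angle, then over r
oracle_F <- function(model, r, theta) {
  tab <- model$anisotropy_table
  rr <- tab$radii_cm; aa <- tab$angles_deg
  at_r <- function(ri) stats::approx(aa, tab$F_values[ri, ], xout = theta,
                                     rule = 2)$y
  rc <- min(max(r, rr[1]), rr[length(rr)])
  if (length(rr) == 1) return(at_r(1))
  i <- max(which(rr <= rc)); i <- min(i, length(rr) - 1)
  w <- (rc - rr[i]) / (rr[i + 1] - rr[i])
  (1 - w) * at_r(i) + w * at_r(i + 1)
}

oracle_dose_rate <- function(model, r, theta) {
  model$air_kerma_strength * model$dose_rate_constant * (1 / r^2) /
    (1 / 1^2) * oracle_g(model, r) * oracle_F(model, r, theta)
}

# brute-force pellet-train sum; theta measured from the tip direction
oracle_train_dose <- function(config, library, q) {
  total <- 0
  u_tip <- if (config$theta_zero == "tip") -config$axis else config$axis
  for (i in seq_len(config$n_slots)) {
    if (!config$active_flags[i]) next
    center <- (config$tip_position_cm + (i - 1) * config$pellet_pitch_cm) *
      config$axis
    v <- q - center
    r <- sqrt(sum(v^2))
    theta <- acos(min(max(sum(v * u_tip) / r, -1), 1)) * 180 / pi
    m <- library$models[[as.character(i)]]
    if (is.null(m)) m <- library$default_model
    total <- total + oracle_dose_rate(m, r, theta)
  }
  total
}

# random but valid TG-43U1 parameter set (uses the caller's RNG stream)
random_source_model <- function(position_index = NA_integer_) {
  radii <- sort(unique(round(c(1, runif(5, 0.3, 12)), 4)))
  g <- runif(length(radii), 0.6, 1.3)
  g[radii == 1] <- 1
  frad <- sort(unique(round(runif(3, 0.5, 10), 3)))
  fang <- sort(unique(round(c(90, runif(6, 2, 178)), 3)))
  Fm <- matrix(runif(length(frad) * length(fang), 0.8, 1.15),
               length(frad), length(fang))
  Fm[, fang == 90] <- 1
  source_model(
    dose_rate_constant = runif(1, 0.5, 2),
    air_kerma_strength = runif(1, 0.5, 5),
    radial_table = radial_dose_table(radii, g),
    anisotropy_table = anisotropy_table(frad, fang, Fm),
    position_index = position_index)
}

# isotropic unit model: g = 1 and F = 1 over a wide range, Sk = Lambda = 1
isotropic_model <- function(sk = 1, lambda = 1) {
  source_model(
    dose_rate_constant = lambda,
    air_kerma_strength = sk,
    radial_table = radial_dose_table(c(0.05, 100), c(1, 1)),
    anisotropy_table = anisotropy_table(c(0.05, 100), c(1, 90, 179),
                                        matrix(1, 2, 3)))
}

# random evaluation point outside every pellet of a config
random_point_outside <- function(config, box = 4) {
  centers <- pellet_centers(config)
  repeat {
    q <- runif(3, -box, box)
    d <- sqrt(rowSums((matrix(q, nrow(centers), 3, byrow = TRUE) - centers)^2))
    if (all(d > 0.2)) return(q)
  }
}

# even-odd ray-crossing point-in-polygon (closed polyline)
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}
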
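test_that("grid voxels equal direct engine evaluation", {
  m <- cs137_pellet_model()
  cfg <- train_configuration(rep(TRUE, 10))
  eng <- tg43_train_engine(cfg, m)
  # one-voxel region
  g1 <- compute_grid(eng, c(1.3, 1.3), c(0, 0), c(0.7, 0.7))
  expect_equal(as.numeric(g1$values),
               suppressWarnings(train_dose(cfg, m, c(1.3, 0, 0.7))),
               tolerance = 1e-14)
  # spot-check voxels of a longitudinal-plane grid
  gp <- compute_grid(eng, c(-2, 2), c(0, 0), c(-2, 4), spacing = 0.25)
  set.seed(8)
  for (k in 1:12) {
    i <- sample(length(gp$x), 1); j <- sample(length(gp$z), 1)
    want <- tryCatch(suppressWarnings(train_dose(cfg, m, c(gp$x[i], 0, gp$z[j]))),
                     error = function(e) NA_real_)
    expect_equal(gp$values[i, 1, j], want, tolerance = 1e-14)
  }
  expect_true(any(gp$mask))  # voxels inside pellets are masked
})

test_that("an isotropic single pellet renders the analytic inverse-square field", {
  eng <- tg43_train_engine(train_configuration(TRUE), isotropic_model())
  g <- compute_grid(eng, c(-2, 2), c(0, 0), c(-2, 2), spacing = 0.5)
  for (i in seq_along(g$x)) for (j in seq_along(g$z)) {
    r2 <- g$x[i]^2 + g$z[j]^2
    if (sqrt(r2) < 0.2) next
    expect_equal(g$values[i, 1, j], 1 / r2, tolerance = 1e-12)
  }
})

test_that("percent difference is zero on identity, +30 on a 1.3 factor, and masked safely", {
  eng <- tg43_train_engine(train_configuration(rep(TRUE, 5)),
                           cs137_pellet_model())
  a <- compute_grid(eng, c(-1.5, 1.5), c(0, 0), c(-1.5, 2.5), spacing = 0.25)
  expect_true(all(percent_difference(a, a)$values[!a$mask] == 0))
  b <- a; b$values <- 1.3 * a$values
  pd <- percent_difference(a, b)
  expect_equal(pd$values[!pd$mask], rep(30, sum(!pd$mask)), tolerance = 1e-12)
  expect_true(all(pd$mask == a$mask))
  shifted <- compute_grid(eng, c(-1.5, 1.5), c(0, 0), c(-1.25, 2.75),
                          spacing = 0.25)
  expect_error(percent_difference(a, shifted), "congruent")
})

test_that("TG-43 vs legacy percent difference matches the closed-form single-pellet ratio", {
  m <- cs137_pellet_model()
  cfg <- train_configuration(TRUE)
  lp <- legacy_parameters(activity_mCi = 2)
  a <- compute_grid(tg43_train_engine(cfg, m), c(0.5, 3), c(0, 0), c(0, 0),
                    spacing = 0.5)
  b <- compute_grid(legacy_train_engine(cfg, lp), c(0.5, 3), c(0, 0), c(0, 0),
                    spacing = 0.5)
  pd <- percent_difference(a, b)
  Tr <- function(r) sum(lp$attenuation_coeffs * r^(0:3))
  for (i in seq_along(a$x)) {
    r <- a$x[i]
    # geometry factors cancel: ratio is [f*Gamma*A*T(r)] / [Sk*Lambda*g*F]
    want <- 100 * ((lp$f_factor * lp$exposure_rate_constant *
                      lp$activity_mCi * Tr(r)) /
                     (m$air_kerma_strength * m$dose_rate_constant *
                        suppressWarnings(eval_g(m$radial_table, r)) *
                        suppressWarnings(eval_F(m$anisotropy_table, r, 90))) - 1)
    expect_equal(pd$values[i, 1, 1], want, tolerance = 1e-10)
  }
})

test_that("isodose contours of an inverse-square field are circles", {
  eng <- tg43_train_engine(train_configuration(TRUE), isotropic_model())
  g <- compute_grid(eng, c(-2.5, 2.5), c(0, 0), c(-2.5, 2.5), spacing = 0.125)
  r0 <- 1.5
  ctr <- isodose_contours(g, levels = 1 / r0^2)
  expect_length(ctr, 1L)
  expect_gte(length(ctr[[1]]), 1L)
  for (seg in ctr[[1]]) {
    rad <- sqrt(seg$x^2 + seg$z^2)
    expect_lt(max(abs(rad - r0)), 0.125)
  }
})

test_that("levels outside the grid range give empty polyline lists, not errors", {
  eng <- tg43_train_engine(train_configuration(TRUE), isotropic_model())
  g <- compute_grid(eng, c(1, 2), c(0, 0), c(1, 2), spacing = 0.25)
  ctr <- isodose_contours(g, levels = c(1e6, 1e-9))
  expect_length(ctr[[1]], 0L)
  expect_length(ctr[[2]], 0L)
  # constant field has no contours at any other level
  gc <- g; gc$values[] <- 5
  expect_length(suppressWarnings(isodose_contours(gc, levels = 4.9))[[1]], 0L)
})

test_that("a low-level contour around two pellets is one closed curve enclosing both", {
  cfg <- train_configuration(c(TRUE, TRUE), pellet_pitch_cm = 2)
  eng <- tg43_train_engine(cfg, isotropic_model())
  g <- compute_grid(eng, c(-4, 4), c(0, 0), c(-3, 5), spacing = 0.125)
  level <- 0.2  # low enough that the two unit sources merge
  ctr <- isodose_contours(g, levels = level)[[1]]
  expect_length(ctr, 1L)
  seg <- ctr[[1]]
  expect_equal(c(seg$x[1], seg$z[1]),
               c(seg$x[nrow(seg)], seg$z[nrow(seg)]), tolerance = 1e-9)
  expect_true(point_in_polygon(0, 0, seg$x, seg$z))
  expect_true(point_in_polygon(0, 2, seg$x, seg$z))
  # vertices bracket the level: dose just inside > level > just outside
  centroid <- c(mean(seg$x), mean(seg$z))
  for (i in seq(1, nrow(seg), by = 7)) {
    v <- c(seg$x[i], seg$z[i])
    inward <- v + 0.1 * (centroid - v) / sqrt(sum((centroid - v)^2))
    outward <- v - 0.15 * (centroid - v) / sqrt(sum((centroid - v)^2))
    expect_gt(eng(c(inward[1], 0, inward[2])), level)
    expect_lt(eng(c(outward[1], 0, outward[2])), level)
  }
})

test_that("contours are written as delimited polyline files", {
  eng <- tg43_train_engine(train_configuration(TRUE), isotropic_model())
  g <- compute_grid(eng, c(-2, 2), c(0, 0), c(-2, 2), spacing = 0.25)
  ctr <- isodose_contours(g, levels = c(1, 0.5))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_contours(ctr, p)
  df <- utils::read.delim(p)
  expect_named(df, c("level", "polyline", "x", "z"))
  expect_setequal(unique(df$level), c(1, 0.5))
})

test_that("axial profile of a single isotropic pellet is inverse-square beyond the tip", {
  cfg <- train_configuration(TRUE)   # pellet center at origin, tip at -0.125
  eng <- tg43_train_engine(cfg, isotropic_model(sk = 2, lambda = 1.5))
  prof <- suppressWarnings(axial_profile(eng, cfg, distances_cm = c(0.5, 1, 2, 4)))
  # distance from pellet center = beyond-tip distance + pellet radius
  expect_equal(prof$dose_cGy_h, 3 / (prof$distance_cm + 0.125)^2,
               tolerance = 1e-12)
})

test_that("axial profiles decrease monotonically beyond the last active pellet", {
  m <- cs137_pellet_model()
  cfg <- train_configuration(rep(TRUE, 10))
  lp <- calibrate_legacy(legacy_parameters(), m)
  d <- seq(0.25, 6, by = 0.25)
  pt <- suppressWarnings(axial_profile(tg43_train_engine(cfg, m), cfg, d))
  pl <- suppressWarnings(axial_profile(legacy_train_engine(cfg, lp), cfg, d))
  expect_true(all(diff(pt$dose_cGy_h) < 0))
  expect_true(all(diff(pl$dose_cGy_h) < 0))
  # off-axis profile line also supported
  po <- suppressWarnings(axial_profile(tg43_train_engine(cfg, m), cfg, d,
                                       radial_offset_cm = 1))
  expect_true(all(is.finite(po$dose_cGy_h)))
})

test_that("the legacy engine overestimates dose toward the applicator tip", {
  m <- cs137_pellet_model()
  cfg <- train_configuration(rep(TRUE, 10))
  lp <- calibrate_legacy(legacy_parameters(), m)
  et <- tg43_train_engine(cfg, m)
  el <- legacy_train_engine(cfg, lp)
  d <- c(0.5, 1, 1.5, 2)
  pt <- suppressWarnings(axial_profile(et, cfg, d))$dose_cGy_h
  pl <- suppressWarnings(axial_profile(el, cfg, d))$dose_cGy_h
  expect_true(all(pl > pt))
  pd <- 100 * (pl - pt) / pt
  expect_gt(pd[which(d == 1)], 5)  # clearly positive, not a rounding artifact
})

test_that("planar grids write as matrices with a sidecar header", {
  eng <- tg43_train_engine(train_configuration(TRUE), isotropic_model())
  g <- compute_grid(eng, c(0.5, 1.5), c(0, 0), c(0.5, 1.5), spacing = 0.5)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_dose_grid(g, p)
  mat <- as.matrix(utils::read.delim(p, header = FALSE))
  expect_identical(dim(mat), c(3L, 3L))
  expect_equal(mat[1, 1], 1 / (0.5^2 + 0.5^2), tolerance = 1e-12,
               ignore_attr = TRUE)
  hdr <- readLines(paste0(p, ".hdr"))
  expect_match(hdr[1], "origin_cm = 0.5 0 0.5")
  expect_match(hdr[3], "shape = 3 1 3")
})
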
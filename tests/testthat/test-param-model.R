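test_that("packaged pellet parameter file loads with the published table shapes", {
  m <- cs137_pellet_model()
  expect_s3_class(m, "source_model")
  expect_length(m$radial_table$radii_cm, 10L)
  expect_identical(m$radial_table$radii_cm, as.numeric(1:10))
  expect_identical(dim(m$anisotropy_table$F_values), c(3L, 11L))
  expect_identical(m$anisotropy_table$radii_cm, c(3, 5, 7))
  expect_identical(m$anisotropy_table$angles_deg, seq(15, 165, by = 15))
  expect_identical(m$position_index, 1L)
})

test_that("interpolators are node-exact over the whole packaged tables", {
  m <- cs137_pellet_model()
  g <- m$radial_table
  expect_identical(eval_g(g, g$radii_cm), g$g_values)
  f <- m$anisotropy_table
  for (i in seq_along(f$radii_cm))
    expect_identical(eval_F(f, rep(f$radii_cm[i], length(f$angles_deg)),
                            f$angles_deg),
                     unname(f$F_values[i, ]))
  # spot values at printed precision
  expect_equal(eval_g(g, 10), 0.865)
  expect_equal(eval_g(g, 1), 1.000)
  expect_equal(eval_F(f, 3, 15), 0.903)
  expect_equal(eval_F(f, 7, 165), 0.938)
  expect_equal(eval_F(f, 5, 90), 1.0)
})

test_that("g interpolation is linear between nodes and continuous at nodes", {
  g <- cs137_pellet_model()$radial_table
  expect_equal(eval_g(g, 2.5), (0.998 + 0.985) / 2)  # 0.9915
  for (r in g$radii_cm[2:9]) {
    eps <- 1e-9
    expect_lt(abs(eval_g(g, r - eps) - eval_g(g, r + eps)), 1e-7)
  }
})

test_that("F interpolation is bilinear and continuous", {
  f <- cs137_pellet_model()$anisotropy_table
  # midpoint in r between F(3,45) = 1 and F(5,45) = 0.996
  expect_equal(eval_F(f, 4, 45), 0.998)
  # midpoint in theta at a tabulated radius
  expect_equal(eval_F(f, 3, 22.5), (0.903 + 0.956) / 2)
  # interior bilinear point against the four surrounding nodes
  expect_equal(eval_F(f, 4, 52.5),
               mean(c(1.000, 0.999, 0.996, 0.992)))
  eps <- 1e-9
  expect_lt(abs(eval_F(f, 5 - eps, 100) - eval_F(f, 5 + eps, 100)), 1e-7)
  expect_lt(abs(eval_F(f, 4, 120 - eps) - eval_F(f, 4, 120 + eps)), 1e-7)
})

test_that("evaluation outside the tabulated range clamps to the edge with a warning", {
  m <- cs137_pellet_model()
  expect_warning(v <- eval_g(m$radial_table, 15), "clamped")
  expect_identical(v, 0.865)
  expect_warning(v <- eval_g(m$radial_table, 0.2), "clamped")
  expect_identical(v, 1.0)
  expect_warning(v <- eval_F(m$anisotropy_table, 9, 90), "radii")
  expect_identical(v, 1.0)
  expect_warning(v <- eval_F(m$anisotropy_table, 3, 5), "angles")
  expect_identical(v, 0.903)
  expect_warning(v <- eval_F(m$anisotropy_table, 3, 175), "angles")
  expect_identical(v, 0.902)
  for (delta in c(1e-6, 0.5, 3, 100))
    expect_identical(suppressWarnings(eval_g(m$radial_table, 10 + delta)),
                     0.865)
})

test_that("domain errors are raised for invalid evaluation arguments", {
  m <- cs137_pellet_model()
  expect_error(eval_g(m$radial_table, 0), "> 0")
  expect_error(eval_g(m$radial_table, -1), "> 0")
  expect_error(eval_F(m$anisotropy_table, 0, 90), "> 0")
  expect_error(eval_F(m$anisotropy_table, 3, -5), "\\[0, 180\\]")
  expect_error(eval_F(m$anisotropy_table, 3, 181), "\\[0, 180\\]")
})

test_that("table constructors enforce the TG-43U1 normalization invariants", {
  expect_s3_class(radial_dose_table(c(1, 2, 3), c(1.0, 0.9, 0.8)),
                  "radial_dose_table")
  expect_error(radial_dose_table(c(1, 2, 3), c(0.99, 0.9, 0.8)),
               "normalized")
  expect_error(radial_dose_table(c(1, 3, 2), c(1, 0.9, 0.8)), "increasing")
  expect_error(radial_dose_table(c(-1, 2, 3), c(1, 0.9, 0.8)), "> 0")
  expect_error(radial_dose_table(c(1, 2, 3), c(1, -0.9, 0.8)), "> 0")
  expect_error(anisotropy_table(c(3, 5), c(45, 90), matrix(c(1, 1, 1, 0.99), 2)),
               "normalized")
  expect_error(anisotropy_table(c(3, 5), c(90, 45), matrix(1, 2, 2)),
               "increasing")
  expect_error(anisotropy_table(c(3, 5), c(45, 90), matrix(1, 3, 2)),
               "dimensions")
  # without a 90-degree grid angle no normalization check applies
  expect_s3_class(anisotropy_table(c(3, 5), c(45, 135),
                                   matrix(c(0.9, 0.95, 1.02, 1.01), 2)),
                  "anisotropy_table")
})

test_that("malformed parameter files are rejected with informative messages", {
  write_file <- function(lines) {
    p <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
    writeLines(lines, p)
    p
  }
  base <- c("[meta]", "lambda = 1", "sk = 1", "[g]", "1 1.0", "2 0.9",
            "[F]", "45 90 135", "3 0.9 1.0 1.05")
  expect_s3_class(load_parameter_file(write_file(base)), "source_model")

  bad_norm <- base; bad_norm[5] <- "1 0.99"
  expect_error(load_parameter_file(write_file(bad_norm)),
               "g\\(r0 = 1 cm\\) = 0.99")
  bad_f <- base; bad_f[9] <- "3 0.9 0.98 1.05"
  expect_error(load_parameter_file(write_file(bad_f)), "F\\(r = 3")
  expect_error(load_parameter_file(write_file(base[-(1:3)])), "missing \\[meta\\]")
  expect_error(load_parameter_file(write_file(base[-(7:9)])), "missing \\[F\\]")
  nonmono <- c(base[1:5], "0.5 1.2", base[6:9])
  expect_error(load_parameter_file(write_file(nonmono)), "increasing")
  expect_error(load_parameter_file(write_file(c(base, "3 oops"))),
               "non-numeric|1 \\+ n_angles")
})

test_that("parameter file round trip preserves all numeric content exactly", {
  m <- cs137_pellet_model()
  p <- withr::local_tempfile(fileext = ".txt")
  write_parameter_file(m, p)
  m2 <- load_parameter_file(p)
  expect_identical(m2$radial_table$radii_cm, m$radial_table$radii_cm)
  expect_identical(m2$radial_table$g_values, m$radial_table$g_values)
  expect_identical(m2$anisotropy_table$angles_deg, m$anisotropy_table$angles_deg)
  expect_equal(m2$anisotropy_table$F_values, m$anisotropy_table$F_values)
  expect_identical(m2$dose_rate_constant, m$dose_rate_constant)
  expect_identical(m2$air_kerma_strength, m$air_kerma_strength)
  expect_identical(m2$position_index, m$position_index)

  set.seed(7)
  for (k in 1:5) {
    mr <- random_source_model(position_index = k)
    write_parameter_file(mr, p)
    mr2 <- load_parameter_file(p)
    expect_equal(mr2$radial_table$g_values, mr$radial_table$g_values,
                 tolerance = 1e-15)
    expect_equal(mr2$anisotropy_table$F_values, mr$anisotropy_table$F_values,
                 tolerance = 1e-15)
    expect_equal(mr2$dose_rate_constant, mr$dose_rate_constant,
                 tolerance = 1e-15)
  }
})

test_that("source library falls back to the default model for unmapped slots", {
  set.seed(11)
  m1 <- random_source_model(position_index = 1L)
  m3 <- random_source_model(position_index = 3L)
  default <- random_source_model()
  lib <- source_library(default, list(m1, m3))
  expect_identical(model_for_slot(lib, 1), m1)
  expect_identical(model_for_slot(lib, 3), m3)
  expect_identical(model_for_slot(lib, 2), default)
  expect_identical(model_for_slot(lib, 48), default)
  expect_error(source_library(default, list(random_source_model())),
               "position_index")
})

test_that("bilinear interpolation agrees with an independent implementation inside the grid", {
  skip_if_not_installed("pracma")
  set.seed(61)
  for (k in 1:10) {
    m <- random_source_model()
    f <- m$anisotropy_table
    r <- runif(8, min(f$radii_cm), max(f$radii_cm))
    th <- runif(8, min(f$angles_deg), max(f$angles_deg))
    expect_equal(eval_F(f, r, th),
                 pracma::interp2(x = f$angles_deg, y = f$radii_cm,
                                 Z = f$F_values, xp = th, yp = r,
                                 method = "linear"),
                 tolerance = 1e-12)
  }
})

test_that("randomized valid tables are node-exact under the interpolators", {
  set.seed(23)
  for (k in 1:20) {
    m <- random_source_model()
    g <- m$radial_table
    expect_identical(eval_g(g, g$radii_cm), g$g_values)
    f <- m$anisotropy_table
    idx <- cbind(sample(length(f$radii_cm), 5, replace = TRUE),
                 sample(length(f$angles_deg), 5, replace = TRUE))
    expect_identical(eval_F(f, f$radii_cm[idx[, 1]], f$angles_deg[idx[, 2]]),
                     unname(f$F_values[idx]))
  }
})
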
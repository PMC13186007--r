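# Synthetic-data generators: spec validation, determinism, ground-truth
# consistency, and the statistical round trips the analysis relies on.

test_that("section spec validates its invariants", {
  expect_error(section_spec(length_um = 200), "at least one region")
  expect_error(section_spec(px_per_um = 0), "positive")
  expect_error(section_spec(orr_field = 1.2), "\\[0, 1\\)")
  expect_error(section_spec(outer_fractions = c(OS = 0.5, IS = 0.5,
                                                ONL = 0.5, OPL = 0.5)),
               "sum to 1")
  expect_error(section_spec(treated_mixture = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
})

test_that("a constant ORr field yields that ORr in every region", {
  sec <- generate_section(section_spec(length_um = 500, px_per_um = 2,
                                       orr_field = 0.5, seed = 1))
  expect_equal(sec$truth$regions$orr_true, c(0.5, 0.5))
  # and the rendered mask reproduces it within half a pixel of thickness
  prof <- profile_from_mask(sec$label_mask, 2)
  mr <- measure_regions(prof)
  expect_equal(mr$mean_orr, c(0.5, 0.5), tolerance = 0.5 / (2 * 90))
})

test_that("noiseless density truth evaluates the model equation", {
  nm <- list(A_db = 20.86, B_db = 25.56, residual_sd_db = 0,
             radius_um = 2, inl_per_mm = 420, gcl_per_mm = 60)
  sec <- generate_section(section_spec(length_um = 250, px_per_um = 1,
                                       orr_field = 0.44,
                                       nuclei_model = nm, seed = 2),
                          render = FALSE)
  expect_equal(sec$truth$regions$onl_density_true, 10^3.21064,
               tolerance = 1e-9)
  expect_equal(sec$truth$regions$onl_density_true, 1624.2,
               tolerance = 1e-4)
})

test_that("generation is a pure function of (spec, seed)", {
  s1 <- generate_section(section_spec(length_um = 500, px_per_um = 1,
                                      condition = "treated", seed = 33))
  s2 <- generate_section(section_spec(length_um = 500, px_per_um = 1,
                                      condition = "treated", seed = 33))
  expect_identical(s1$images, s2$images)
  expect_identical(s1$truth$regions, s2$truth$regions)
  expect_identical(s1$truth$nuclei, s2$truth$nuclei)

  r1 <- generate_cortical(82.43, seed = 5)
  r2 <- generate_cortical(82.43, seed = 5)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$truth, r2$truth)
})

test_that("control ORr draws respect the truncated normal range", {
  sec <- generate_section(section_spec(length_um = 200 * 250,
                                       px_per_um = 0.02,
                                       condition = "control", seed = 6),
                          render = FALSE)
  orr <- sec$truth$regions$orr_true
  expect_true(all(orr >= 0.39 & orr <= 0.69))
  expect_equal(mean(orr), 0.55, tolerance = 0.02)
  expect_true(all(sec$truth$regions$group_true == 0L))
})

test_that("every rendered nucleus lies inside its declared layer band", {
  sec <- generate_section(section_spec(length_um = 500, px_per_um = 2,
                                       condition = "treated",
                                       orr_field = 0.4, seed = 13))
  nuc <- sec$truth$nuclei
  prof <- sec$truth$profile
  bands <- list(ONL = c("OPL_ONL", "ONL_IS"), INL = c("IPL_INL", "INL_OPL"),
                GCL = c("ILM", "GCL_IPL"))
  x_cl <- pmin(pmax(nuc$x_um, prof$extent[1]), prof$extent[2])
  violations <- 0L
  for (i in seq_len(nrow(nuc))) {
    b <- bands[[nuc$layer[i]]]
    d <- orrquant:::.boundary_depths(prof, x_cl[i])
    if (nuc$depth_um[i] < d[[b[1]]] - 1e-6 ||
        nuc$depth_um[i] > d[[b[2]]] + 1e-6)
      violations <- violations + 1L
  }
  expect_gt(nrow(nuc), 100)
  expect_equal(violations, 0L)
})

test_that("ONL density round trip recovers the model parameters", {
  sec <- generate_section(section_spec(length_um = 500 * 250,
                                       px_per_um = 0.02,
                                       condition = "treated",
                                       correlation_length_um = 0,
                                       seed = 500),
                          render = FALSE)
  r <- sec$truth$regions
  keep <- r$onl_target_count > 0
  fit <- fit_onl_density(r$orr_true[keep],
                         r$onl_target_count[keep] / 0.25)
  expect_lt(abs(fit$A - 20.86), 2 * fit$se[1])
  expect_lt(abs(fit$B - 25.56), 2 * fit$se[2])
})

test_that("cortical group means land on the requested group mean", {
  b <- generate_cortical_battery(n_per_group = 200,
                                 group_means = c(`0` = 82.43),
                                 seed = 7, n_channels = 4,
                                 noise = "none")
  m <- mean(b$electrodes$true_threshold_uA)
  mc_se <- sd(b$electrodes$true_threshold_uA) / sqrt(200)
  expect_lt(abs(m - 82.43), 3 * mc_se)
})

test_that("written sections round-trip through TIFF/CSV/JSON", {
  sec <- generate_section(section_spec(length_um = 250, px_per_um = 1,
                                       orr_field = 0.5, seed = 3))
  dir <- tempfile("sec_")
  paths <- write_section(sec, dir)
  expect_true(all(file.exists(paths)))
  pages <- tiff::readTIFF(paths[["tiff"]], all = TRUE)
  expect_length(pages, 7L)
  expect_equal(pages[[2]], sec$images$dapi, tolerance = 1 / 65535)
  truth <- utils::read.csv(paths[["regions"]])
  expect_equal(truth$orr_true, sec$truth$regions$orr_true,
               tolerance = 1e-6)
  params <- jsonlite::read_json(paths[["params"]])
  expect_equal(params$length_um, 250)
  unlink(dir, recursive = TRUE)
})
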
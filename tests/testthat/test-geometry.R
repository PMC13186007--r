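# Layer geometry: thickness sums, region segmentation, ORr sampling,
# and agreement with per-pixel counting on rendered sections.

flat <- flat_profile(c(OS = 20, IS = 20, ONL = 40, OPL = 20,
                       INL = 30, IPL = 50, GCL = 20), extent_um = 1000)

test_that("layer thicknesses sum into OR and total", {
  th <- layer_thicknesses(flat, 500)
  expect_equal(th[["OR"]], 100)
  expect_equal(th[["total"]], 200)
  expect_equal(th[["orr"]], 0.5)

  no_onl <- flat_profile(c(OS = 20, IS = 20, ONL = 0, OPL = 20,
                           INL = 30, IPL = 50, GCL = 20),
                         extent_um = 1000)
  th0 <- layer_thicknesses(no_onl, 500)
  expect_equal(th0[["OR"]], 60)
  expect_equal(th0[["total"]], 160)

  expect_error(layer_thicknesses(flat, 1500), "outside")
})

test_that("crossing boundaries are rejected with a diagnostic", {
  d <- matrix(c(0, 0, 20, 20, 70, 10, 100, 100, 120, 120, 160, 160,
                180, 180, 200, 200), nrow = 2,
              dimnames = list(NULL, orr_boundaries))
  expect_error(layer_profile(c(0, 100), d), "cross")
})

test_that("regions are adjacent, left-aligned, remainder dropped", {
  expect_equal(nrow(segment_regions(flat)), 4L)
  w <- segment_regions(flat_profile(c(ONL = 10, INL = 10), 1100))
  expect_equal(nrow(w), 4L)
  expect_equal(attr(w, "dropped_um"), 100)
  expect_equal(w$x_start_um, c(0, 250, 500, 750))
  expect_error(segment_regions(flat_profile(c(ONL = 10), 240)),
               "shorter than one region")
})

test_that("region ORr is the mean of midpoint samples", {
  rm <- region_orr(flat, 0)
  expect_equal(rm$sample_x, c(25, 75, 125, 175, 225))
  expect_equal(rm$mean_orr, 0.5)
  expect_equal(rm$sd_orr, 0)
  expect_equal(rm$mean_orr, mean(rm$sample_orr))

  # the sample set {0.44..0.48} averages 0.46 (an intact treated region)
  expect_equal(mean(c(0.44, 0.45, 0.46, 0.47, 0.48)), 0.46)

  # fencepost scheme shares samples with neighbours, midpoint never does
  rf <- region_orr(flat, 0, scheme = "fencepost")
  expect_equal(length(rf$sample_orr), 6L)
})

test_that("midpoint sampling of a linear taper recovers the mid-window value", {
  # ORr falls linearly along the section; symmetric samples average to
  # the centre value
  x <- seq(0, 1000, by = 1)
  inner <- 100
  orr <- 0.6 - 0.0002 * x
  total <- inner / (1 - orr)
  outer <- total - inner
  depths <- cbind(ILM = 0, GCL_IPL = 20, IPL_INL = 60, INL_OPL = inner,
                  OPL_ONL = inner + 0.2 * outer,
                  ONL_IS = inner + 0.7 * outer,
                  IS_OS = inner + 0.85 * outer, OS_EDGE = inner + outer)
  prof <- layer_profile(x, depths)
  rm <- region_orr(prof, 250)
  mid_val <- 0.6 - 0.0002 * 375
  expect_equal(rm$mean_orr, mid_val, tolerance = 1e-6)
})

test_that("ORr is scale invariant and bounded in [0, 1]", {
  set.seed(42)
  for (i in 1:10) {
    th <- stats::runif(7, 5, 60)
    names(th) <- orr_layers
    p1 <- flat_profile(th, 500)
    c_scale <- stats::runif(1, 0.2, 5)
    p2 <- flat_profile(th * c_scale, 500)
    o1 <- layer_thicknesses(p1, 250)[["orr"]]
    o2 <- layer_thicknesses(p2, 250)[["orr"]]
    expect_equal(o1, o2, tolerance = 1e-12)
    expect_gte(o1, 0); expect_lte(o1, 1)
  }
})

test_that("unmeasurable regions (zero total thickness) are flagged", {
  d <- matrix(0, nrow = 2, ncol = 8,
              dimnames = list(NULL, orr_boundaries))
  prof <- layer_profile(c(0, 400), d + 5)   # all boundaries coincide
  rm <- region_orr(prof, 0)
  expect_false(rm$measurable)
  expect_true(is.na(rm$mean_orr))
})

test_that("mask-derived profiles agree with per-pixel counting", {
  sec <- generate_section(section_spec(length_um = 750, px_per_um = 2,
                                       condition = "treated", seed = 21))
  px <- 2
  prof <- profile_from_mask(sec$label_mask, px)
  for (col in c(100, 500, 900, 1300)) {
    oracle <- pixel_count_orr(sec$label_mask, col, px)
    th <- layer_thicknesses(prof, (col - 0.5) / px)
    # within 1 px of the per-column pixel count
    expect_lt(abs(th[["total"]] - oracle[["total_um"]]), 1 / px + 1e-9)
    expect_lt(abs(th[["OR"]] - oracle[["outer_um"]]), 1 / px + 1e-9)
  }
})

test_that("region ORr from the rendered mask matches ground truth", {
  for (seed in c(3, 17)) {
    sec <- generate_section(section_spec(length_um = 1000, px_per_um = 2,
                                         condition = "treated",
                                         seed = seed))
    prof <- profile_from_mask(sec$label_mask, 2)
    mr <- measure_regions(prof, condition = "treated")
    err <- abs(mr$mean_orr - sec$truth$regions$orr_true)
    # mean absolute error at most one pixel-equivalent of thickness ratio
    px_equiv <- 1 / (2 * 90)   # 1 px relative to the inner retina depth
    expect_lt(mean(err), px_equiv)
  }
})

test_that("region tables carry metadata and the partition of samples", {
  mr <- measure_regions(flat, eye_id = "e1", condition = "control",
                        electrode_id = c(NA, "E2", NA, NA),
                        in_pocket = c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(nrow(mr), 4L)
  expect_equal(mr$electrode_id[2], "E2")
  expect_true(all(mr$measurable))
  expect_true(all(mr$mean_orr >= 0 & mr$mean_orr <= 1))
})
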
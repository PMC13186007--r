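# Marker quantification: intensity arithmetic, nuclei counting with
# watershed splitting, positive-nucleus rule, DAB chromatic
# classification, and the group-4 exclusion gate.

test_that("fluorescence intensity is choroid-subtracted and offset invariant", {
  img <- matrix(0, 20, 20)
  target <- matrix(FALSE, 20, 20); target[1:5, ] <- TRUE
  choroid <- matrix(FALSE, 20, 20); choroid[15:20, ] <- TRUE
  img[target] <- 100 / 255; img[choroid] <- 20 / 255
  expect_equal(fluorescence_intensity(img, target, choroid), 80 / 255)

  # identical target and background intensity -> zero
  img2 <- matrix(0.3, 20, 20)
  expect_equal(fluorescence_intensity(img2, target, choroid), 0)

  # adding a constant offset to the whole image cancels out
  expect_equal(fluorescence_intensity(img + 0.1, target, choroid),
               fluorescence_intensity(img, target, choroid))

  # below-background values survive, flagged
  img3 <- img; img3[target] <- 0.01
  v <- fluorescence_intensity(img3, target, choroid)
  expect_lt(v, 0)
  expect_true(isTRUE(attr(v, "below_background")))

  expect_error(fluorescence_intensity(img, target & FALSE, choroid),
               "empty")
  expect_error(fluorescence_intensity(img, target, target), "overlap")
})

test_that("control normalization divides by the control mean", {
  expect_equal(normalize_to_control(80, c(70, 90)), 1)
  expect_equal(normalize_to_control(40, c(80, 80)), 0.5)
  expect_error(normalize_to_control(40, c(-1, 1)), "positive")
})

test_that("disjoint nuclei are counted exactly; touching ones split", {
  # 12 disjoint disks on a 3 x 4 grid
  centers <- as.matrix(expand.grid(row = c(15, 35, 55),
                                   col = c(15, 40, 65, 90)))
  img <- disk_image(70, 105, centers, r_px = 4)
  mask <- matrix(TRUE, 70, 105)
  ns <- count_nuclei(img, mask, px_per_um = 1)
  expect_equal(ns$count, 12L)
  # per-mm normalization: 105 px wide at 1 px/um
  expect_equal(ns$count_per_mm, 12 / (105 / 1000))

  # two overlapping disks with distinct centres: watershed gives 2
  two <- disk_image(30, 40, rbind(c(15, 12), c(15, 21)), r_px = 5)
  ns2 <- count_nuclei(two, matrix(TRUE, 30, 40), px_per_um = 1)
  expect_equal(ns2$count, 2L)

  expect_error(count_nuclei(img, mask & FALSE, 1), "empty")
})

test_that("the circularity window excludes elongated blobs", {
  img <- disk_image(40, 100, rbind(c(12, 15), c(12, 40)), r_px = 5)
  img[25:29, 10:90] <- 0.9   # a long bar, circularity far below disks
  mask <- matrix(TRUE, 40, 100)
  all_objects <- count_nuclei(img, mask, 1)
  expect_equal(all_objects$count, 3L)
  round_only <- count_nuclei(img, mask, 1, circularity = c(0.8, 1))
  expect_equal(round_only$count, 2L)
  # defaults (min_area 0, circularity [0,1]) impose no filtering
  expect_equal(all_objects$count,
               count_nuclei(img, mask, 1, min_area_um2 = 0,
                            circularity = c(0, 1))$count)
})

test_that("positive nuclei require the overlap fraction in the marker channel", {
  centers <- rbind(c(15, 15), c(15, 45))
  img <- disk_image(30, 60, centers, r_px = 4)
  ns <- count_nuclei(img, matrix(TRUE, 30, 60), 1)
  expect_equal(ns$count, 2L)

  # all-zero marker channel: none positive (and a range warning)
  zero <- matrix(0, 30, 60)
  expect_warning(n_zero <- positive_nuclei(ns, zero, 0.5), "outside")
  expect_equal(as.integer(n_zero), 0L)

  # saturated marker: all positive
  sat <- matrix(1, 30, 60)
  expect_equal(as.integer(suppressWarnings(
    positive_nuclei(ns, sat, 0.5))), 2L)

  # marker covering only the first nucleus
  half <- matrix(0, 30, 60); half[, 1:30] <- 1
  expect_equal(as.integer(positive_nuclei(ns, half, 0.5)), 1L)
})

test_that("ectopic opsin-positive nuclei are recovered from a clean render", {
  sec <- generate_section(section_spec(length_um = 500, px_per_um = 2,
                                       condition = "treated",
                                       orr_field = 0.3, seed = 8))
  nuc <- sec$truth$nuclei
  onl <- nuc[nuc$layer == "ONL", ]
  ect_true <- sum(onl$ectopic)
  expect_gt(ect_true, 0)
  band <- sec$label_mask == 5L
  ns <- count_nuclei(sec$images$dapi, band, 2)
  pos <- positive_nuclei(ns, sec$images$marker, intensity_threshold = 0.5)
  expect_equal(as.integer(pos), ect_true, tolerance = 0.15 * ect_true)
})

test_that("DAB area follows the chromatic rule on constructed fixtures", {
  H <- 60; W <- 250; px <- 1
  mask <- matrix(TRUE, H, W)
  white <- array(1, c(H, W, 3))
  expect_equal(as.numeric(dab_positive_area(white, mask, px)), 0)

  # brown patch of exactly 500 um^2 in a 250 um window -> 2.0 um^2/um
  dab_od <- c(0.268, 0.570, 0.776) / sqrt(sum(c(0.268, 0.570, 0.776)^2))
  patch <- white
  rows <- 21:40; cols <- 101:125           # 20 x 25 px = 500 px^2
  for (ch in 1:3)
    patch[rows, cols, ch] <- 10^-(0.8 * dab_od[ch])
  expect_equal(as.numeric(dab_positive_area(patch, mask, px)), 2.0)

  # haematoxylin-only staining is never DAB positive
  h_od <- c(0.650, 0.704, 0.286) / sqrt(sum(c(0.650, 0.704, 0.286)^2))
  blue <- white
  for (ch in 1:3) blue[rows, cols, ch] <- 10^-(0.9 * h_od[ch])
  expect_equal(as.numeric(dab_positive_area(blue, mask, px)), 0)

  # the hue-window rule agrees on these fixtures
  expect_equal(as.numeric(dab_positive_area(patch, mask, px,
                                            method = "hue")), 2.0)
  expect_equal(as.numeric(dab_positive_area(blue, mask, px,
                                            method = "hue")), 0)

  expect_error(dab_positive_area(white[, , 1], mask, px), "H x W x 3")
})

test_that("DAB area is additive over disjoint masks and ignores padding", {
  sec <- generate_section(section_spec(length_um = 500, px_per_um = 2,
                                       condition = "treated",
                                       orr_field = 0.3, seed = 12))
  ipl <- sec$label_mask == 2L
  left <- ipl; left[, 501:1000] <- FALSE
  right <- ipl; right[, 1:500] <- FALSE
  a_all <- as.numeric(dab_positive_area(sec$images$dab, ipl, 2))
  a_l <- as.numeric(dab_positive_area(sec$images$dab, left, 2))
  a_r <- as.numeric(dab_positive_area(sec$images$dab, right, 2))
  # area (not area-per-length) adds over the disjoint halves
  len <- function(m) diff(range(which(colSums(m) > 0))) + 1
  expect_equal(a_all * len(ipl), a_l * len(left) + a_r * len(right),
               tolerance = 1e-9)
  # altering pixels outside the mask changes nothing
  img2 <- sec$images$dab
  img2[sec$label_mask == 0L] <- 0.123
  expect_equal(as.numeric(dab_positive_area(img2, ipl, 2)), a_all)
})

test_that("rendered DAB area matches the generator ground truth", {
  sec <- generate_section(section_spec(length_um = 500, px_per_um = 2,
                                       condition = "treated",
                                       orr_field = 0.3, seed = 12))
  ipl <- sec$label_mask == 2L
  a <- as.numeric(dab_positive_area(sec$images$dab, ipl, 2))
  truth <- sum(sec$truth$regions$dab_area_true_um2) / 500
  expect_equal(a, truth, tolerance = 0.05)
})

test_that("RBPMS ratio is positive count over total", {
  expect_equal(rbpms_ratio(10, 20), 0.5)
  expect_equal(rbpms_ratio(20, 20), 1)
  expect_error(rbpms_ratio(5, 0), "zero GCL")
  expect_error(rbpms_ratio(25, 20), "\\[0, total\\]")
})

test_that("group-4 and unmeasurable regions are barred from photoreceptor markers", {
  expect_equal(photoreceptor_quantifiable(c(0L, 1L, 3L, 4L, NA)),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_false(photoreceptor_quantifiable(2L, measurable = FALSE))
})
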
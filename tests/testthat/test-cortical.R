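# Cortical metrics: 50%-of-maximum thresholds, best-of-hemispheres
# selection, and d-prime spatial selectivity.

test_that("interpolated threshold hits an exact 50% crossing", {
  currents <- c(0, 100, 200, 300, 400)
  counts <- c(0, 10, 20, 40, 40)
  expect_equal(channel_threshold(currents, counts,
                                 method = "interpolate"), 200)
  # uniform count scaling leaves the threshold unchanged
  expect_equal(channel_threshold(currents, counts * 3,
                                 method = "interpolate"), 200)
})

test_that("sigmoid fitting recovers a known midpoint within 5 uA", {
  currents <- seq(0, 750, by = 50)
  for (mid in c(60, 120, 240)) {
    counts <- 40 * plogis((currents - mid) / 20)
    expect_lt(abs(channel_threshold(currents, counts) - mid), 5)
    expect_lt(abs(channel_threshold(currents, counts * 3) - mid), 5)
  }
})

test_that("non-responsive and malformed inputs are handled", {
  currents <- c(0, 100, 200, 300)
  expect_true(is.na(channel_threshold(currents, c(0, 0, 0, 0))))
  expect_true(is.na(channel_threshold(currents, c(0, 1, 2, 3),
                                      noise_floor = 5)))
  expect_error(channel_threshold(c(0, 100), c(0, 5)), "at least 3")
  expect_error(channel_threshold(c(0, 100, 100), c(0, 5, 10)),
               "strictly increasing")
  expect_error(channel_threshold(currents, c(0, -1, 5, 10)),
               "non-negative")
})

test_that("best threshold is the minimum finite threshold across hemispheres", {
  currents <- c(0, 50, 100, 150, 200)
  mk <- function(mid, M) M * plogis((currents - mid) / 10)
  tab <- make_spike_table(list(
    list(channel = "i1", hemisphere = "ipsi", x = 0,
         counts = mk(90, 40)),
    list(channel = "c1", hemisphere = "contra", x = 0,
         counts = mk(82.4, 40)),
    list(channel = "c2", hemisphere = "contra", x = 1,
         counts = rep(0, 5))), currents)
  bt <- best_threshold(tab)
  expect_equal(as.numeric(bt), 82.4, tolerance = 0.5)
  expect_equal(attr(bt, "hemisphere"), "contra")

  # single responsive channel: its threshold
  one <- make_spike_table(list(
    list(channel = "i1", hemisphere = "ipsi", x = 0,
         counts = mk(120, 30))), currents)
  expect_equal(as.numeric(best_threshold(one)), 120, tolerance = 0.5)

  # nothing responsive: sentinel
  none <- make_spike_table(list(
    list(channel = "i1", hemisphere = "ipsi", x = 0,
         counts = rep(0, 5)),
    list(channel = "i2", hemisphere = "ipsi", x = 1,
         counts = rep(1, 5))), currents)
  expect_true(is.na(best_threshold(none)))
})

test_that("d-prime equals the exact slope on a linear falloff fixture", {
  currents <- c(0, 50, 100, 150, 200)
  ramp <- function(M, onset) ifelse(currents < onset, 0, M)
  tab <- make_spike_table(list(
    list(channel = "a", x = 0, counts = c(0, 20, 40, 40, 40)),
    list(channel = "b", x = 1, counts = c(0, 10, 20, 20, 20)),
    list(channel = "c", x = 2, counts = c(0, 0, 0, 10, 20))), currents)
  # at 200 uA the normalized firing is {1, 0.5, 0.5}; use a map where
  # the third channel fires 0 at the evaluation current instead
  tab2 <- make_spike_table(list(
    list(channel = "a", x = 0, counts = c(0, 20, 40, 40, 40)),
    list(channel = "b", x = 1, counts = c(0, 10, 20, 20, 20)),
    list(channel = "c", x = 2, counts = c(0, 0, 0, 6, 12))), currents)
  sel <- dprime_selectivity(tab2, evaluation_current = 100)
  expect_equal(sel$d_prime, 0.5, tolerance = 1e-9)
  expect_equal(sel$n_channels_used, 3L)

  # spatially uniform firing: d-prime 0
  uni <- make_spike_table(list(
    list(channel = "a", x = 0, counts = c(0, 20, 40, 40, 40)),
    list(channel = "b", x = 1, counts = c(0, 20, 40, 40, 40)),
    list(channel = "c", x = 2, counts = c(0, 20, 40, 40, 40))), currents)
  expect_equal(dprime_selectivity(uni, evaluation_current = 150)$d_prime,
               0, tolerance = 1e-9)

  # uniform count scaling leaves d-prime unchanged
  tab3 <- tab2; tab3$spikes <- tab3$spikes * 7
  expect_equal(dprime_selectivity(tab3, evaluation_current = 100)$d_prime,
               0.5, tolerance = 1e-9)

  expect_error(dprime_selectivity(tab2[tab2$channel != "c", ]),
               "at least 3")
})

test_that("noiseless generated batteries are recovered exactly", {
  r <- generate_cortical(82.43, seed = 1, noise = "none")
  expect_equal(as.numeric(best_threshold(r$table)),
               r$truth$threshold_uA, tolerance = 0.1)
  sel <- dprime_selectivity(r$table)
  expect_equal(sel$d_prime, r$truth$d_prime, tolerance = 0.02)
})

test_that("estimated d-prime increases with the generator falloff rate", {
  est <- vapply(c(0.15, 0.45, 0.8), function(f) {
    mean(vapply(1:6, function(s)
      dprime_selectivity(generate_cortical(90, seed = s, falloff = f,
                                           noise = "none")$table)$d_prime,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("zero falloff gives uniform maps and zero true d-prime", {
  r <- generate_cortical(90, seed = 4, falloff = 0, noise = "none")
  expect_equal(r$truth$d_prime, 0)
  ipsi <- r$table[r$table$hemisphere == "ipsi", ]
  maxima <- tapply(ipsi$spikes, ipsi$channel, max)
  # all ipsilateral channels saturate at the same maximum
  expect_lt(diff(range(maxima)), 1e-9)
  expect_equal(dprime_selectivity(r$table)$d_prime, 0, tolerance = 0.02)
})

test_that("generator rejects non-monotone or invalid requests", {
  expect_error(generate_cortical(-5), "positive")
  expect_error(generate_cortical(80, n_channels = 1), "at least 2")
  expect_error(generate_cortical(80, slope_uA = 0), "monotone")
})
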
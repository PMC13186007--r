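# Electrically evoked cortical metrics: per-channel 50%-of-maximum
# activation thresholds, best-of-hemispheres threshold per stimulating
# electrode, and d-prime spatial selectivity (rate of reduction of
# normalized firing with distance from the best cortical channel).

#' Cortical activation threshold of one recording channel
#'
#' The threshold is the injected current eliciting 50% of the channel's
#' maximum spike count (3-20 ms post-stimulus window). By default a
#' monotone logistic with floor 0 and fitted ceiling,
#' `M * plogis((I - m) / s)`, is least-squares fitted and the current at
#' half the fitted maximum (the midpoint `m`) returned; if the fit fails
#' or lands outside the tested range, the threshold falls back to linear
#' interpolation of the monotone upper envelope of the counts at half the
#' observed maximum. Channels whose maximum count is below `noise_floor`
#' are non-responsive and return `NA`.
#'
#' Thresholds are invariant to uniform scaling of the spike counts.
#'
#' @param currents Strictly increasing stimulus currents (uA), >= 3 levels.
#' @param spike_counts Non-negative spike counts, one per current.
#' @param method `"sigmoid"` (default, with interpolation fallback) or
#'   `"interpolate"`.
#' @param noise_floor Minimum maximum-count for a responsive channel
#'   (default 5 spikes).
#' @return Threshold current (uA), or `NA_real_` for no response.
#' @export
channel_threshold <- function(currents, spike_counts,
                              method = c("sigmoid", "interpolate"),
                              noise_floor = 5) {
  method <- match.arg(method)
  if (length(currents) < 3L) stop("need at least 3 current levels")
  if (length(currents) != length(spike_counts))
    stop("currents and spike_counts must have equal length")
  if (is.unsorted(currents, strictly = TRUE))
    stop("currents must be strictly increasing")
  if (any(spike_counts < 0)) stop("spike counts must be non-negative")
  if (max(spike_counts) < noise_floor) return(NA_real_)
  if (method == "sigmoid") {
    thr <- .sigmoid_threshold(currents, spike_counts)
    if (!is.na(thr)) return(thr)
  }
  .interp_threshold(currents, spike_counts)
}

.sigmoid_threshold <- function(currents, counts) {
  m0 <- .interp_threshold(currents, counts)
  s0 <- max(diff(range(currents)) / 10, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      counts ~ M * stats::plogis((currents - m) / s),
      start = list(M = max(counts), m = m0, s = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  cf <- stats::coef(fit)
  # reject degenerate solutions; the interpolation fallback takes over
  if (!all(is.finite(cf)) || cf[["M"]] <= 0 || cf[["s"]] <= 0 ||
      cf[["M"]] > 10 * max(counts) ||
      cf[["m"]] <= min(currents) || cf[["m"]] >= max(currents))
    return(NA_real_)
  cf[["m"]]
}

.interp_threshold <- function(currents, counts) {
  env <- cummax(counts)            # monotone upper envelope
  half <- max(counts) / 2
  i <- which(env >= half)[1L]
  if (i == 1L) return(currents[1L])
  # linear interpolation between the bracketing levels
  x0 <- currents[i - 1L]; x1 <- currents[i]
  y0 <- env[i - 1L]; y1 <- env[i]
  if (y1 == y0) return(x1)
  x0 + (half - y0) / (y1 - y0) * (x1 - x0)
}

#' Per-channel thresholds for one stimulating electrode
#'
#' @param response Spike table for one stimulating electrode: data frame
#'   with columns `channel`, `hemisphere` ("ipsi"/"contra"), `x_mm`,
#'   `y_mm`, `current_uA`, `spikes` (long format, one row per channel x
#'   current).
#' @inheritParams channel_threshold
#' @return Data frame with one row per channel: `channel`, `hemisphere`,
#'   `x_mm`, `y_mm`, `max_spikes`, `threshold_uA` (NA = no response).
#' @export
channel_thresholds <- function(response, method = c("sigmoid", "interpolate"),
                               noise_floor = 5) {
  method <- match.arg(method)
  .check_spike_table(response)
  out <- do.call(rbind, lapply(split(response, response$channel), function(d) {
    d <- d[order(d$current_uA), ]
    data.frame(channel = d$channel[1L], hemisphere = d$hemisphere[1L],
               x_mm = d$x_mm[1L], y_mm = d$y_mm[1L],
               max_spikes = max(d$spikes),
               threshold_uA = channel_threshold(d$current_uA, d$spikes,
                                                method, noise_floor))
  }))
  rownames(out) <- NULL
  out
}

#' Best cortical threshold across hemispheres
#'
#' The lowest finite channel threshold across the ipsilateral and
#' contralateral recording arrays for one stimulating electrode.
#'
#' @inheritParams channel_thresholds
#' @return Threshold (uA) with attributes `channel` and `hemisphere`;
#'   `NA_real_` when no channel is responsive.
#' @export
best_threshold <- function(response, method = c("sigmoid", "interpolate"),
                           noise_floor = 5) {
  th <- channel_thresholds(response, method, noise_floor)
  ok <- which(is.finite(th$threshold_uA))
  if (!length(ok)) return(NA_real_)
  i <- ok[which.min(th$threshold_uA[ok])]
  structure(th$threshold_uA[i], channel = th$channel[i],
            hemisphere = th$hemisphere[i])
}

#' d-prime cortical spatial selectivity
#'
#' Rate of reduction of normalized cortical firing with distance from the
#' best channel (the channel with the lowest threshold): firing at the
#' evaluation current is taken per responsive channel of the best
#' channel's hemisphere, normalized to the best channel's firing, and
#' regressed on Euclidean distance (mm) from the best channel; d-prime is
#' the negative of the least-squares slope (per mm). Spatially uniform
#' firing gives 0; the estimate is invariant to uniform count scaling.
#'
#' @inheritParams channel_thresholds
#' @param evaluation_current Current (uA) at which the firing map is
#'   taken; default twice the best threshold, capped at the maximum tested
#'   current.
#' @return List of class `selectivity_estimate`: `d_prime` (per mm),
#'   `best_channel`, `hemisphere`, `evaluation_current`,
#'   `n_channels_used`.
#' @export
dprime_selectivity <- function(response, evaluation_current = NULL,
                               method = c("sigmoid", "interpolate"),
                               noise_floor = 5) {
  th <- channel_thresholds(response, method, noise_floor)
  ok <- which(is.finite(th$threshold_uA))
  if (length(ok) < 3L) stop("need at least 3 responsive channels")
  best <- ok[which.min(th$threshold_uA[ok])]
  hemi <- th$hemisphere[best]
  if (is.null(evaluation_current))
    evaluation_current <- min(2 * th$threshold_uA[best],
                              max(response$current_uA))
  use <- th[th$hemisphere == hemi & is.finite(th$threshold_uA), ]
  if (nrow(use) < 3L) stop("need at least 3 responsive channels in the ",
                           "best hemisphere")
  firing <- vapply(use$channel, function(ch) {
    d <- response[response$channel == ch, ]
    d <- d[order(d$current_uA), ]
    stats::approx(d$current_uA, d$spikes, xout = evaluation_current,
                  rule = 2L)$y
  }, numeric(1))
  b <- which(use$channel == th$channel[best])
  if (firing[b] <= 0) stop("zero firing at the best channel")
  norm <- firing / firing[b]
  dist <- sqrt((use$x_mm - use$x_mm[b])^2 + (use$y_mm - use$y_mm[b])^2)
  slope <- if (stats::var(dist) == 0) 0
           else unname(stats::coef(stats::lm(norm ~ dist))[2L])
  structure(list(d_prime = -slope, best_channel = th$channel[best],
                 hemisphere = hemi,
                 evaluation_current = evaluation_current,
                 n_channels_used = nrow(use)),
            class = "selectivity_estimate")
}

#' @export
print.selectivity_estimate <- function(x, ...) {
  cat(sprintf(
    "d' selectivity: %.3f per mm (best channel %s, %s hemisphere, %d channels, eval %.0f uA)\n",
    x$d_prime, x$best_channel, x$hemisphere, x$n_channels_used,
    x$evaluation_current))
  invisible(x)
}

.check_spike_table <- function(response) {
  need <- c("channel", "hemisphere", "x_mm", "y_mm", "current_uA", "spikes")
  miss <- setdiff(need, names(response))
  if (length(miss))
    stop("spike table lacks columns: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}
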
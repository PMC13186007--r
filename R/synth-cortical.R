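# Synthetic cortical spike-count tables for one stimulating electrode:
# monotone logistic recruitment per recording channel, channel maxima
# falling off linearly with distance from the best channel (the
# ground-truth d-prime), and the best channel's true threshold drawn
# around a group mean.

#' Generate a synthetic cortical response
#'
#' Builds the spike-count table of all recording channels (both
#' hemispheres) for one stimulating electrode. Each channel's mean count
#' follows `M_c * plogis((I - t) / slope)`, a monotone sigmoid with floor
#' 0 saturating at a channel-specific maximum `M_c`; the best channel's
#' true 50%-of-maximum current `t` is drawn from a normal around the
#' group mean, and `M_c` falls off linearly with distance from the best
#' channel at rate `falloff` per mm (the ground-truth d-prime). The
#' contralateral hemisphere responds with a higher threshold and reduced
#' maximum, so the ipsilateral best channel defines the best threshold.
#'
#' @param group_mean True mean best threshold (uA) of the electrode's
#'   degeneration group, > 0.
#' @param group_label Group (0-4), metadata only.
#' @param n_channels Total recording channels across both hemispheres,
#'   >= 2.
#' @param seed RNG seed or NULL.
#' @param threshold_sd Between-electrode SD of the true threshold (uA).
#' @param falloff Rate of reduction of normalized firing per mm (>= 0);
#'   0 makes all channels share the best channel's profile (true
#'   d-prime 0).
#' @param slope_uA Sigmoid slope parameter (uA), > 0 (a non-positive
#'   slope would make the sigmoid non-monotone and is rejected).
#' @param threshold_gradient_uA_per_mm Increase of a channel's midpoint
#'   current with distance from its hemisphere's best site (uA/mm), so
#'   the best channel genuinely has the lowest threshold.
#' @param max_spikes Best-channel maximum spike count.
#' @param currents Stimulus currents (uA), strictly increasing; default
#'   0-750 uA in 50 uA steps.
#' @param spacing_mm Recording-array pitch (mm).
#' @param contra_attenuation,contra_threshold_shift_uA Contralateral
#'   maximum scaling and threshold offset.
#' @param noise `"poisson"` (default) for Poisson spike counts or
#'   `"none"` for noiseless mean counts.
#' @return Object of class `cortical_response`: list with `table` (long
#'   data frame: `stim_electrode`, `channel`, `hemisphere`, `x_mm`,
#'   `y_mm`, `current_uA`, `spikes`), `truth` (list: `threshold_uA`,
#'   `d_prime`, `best_channel`, `group`), and the generating parameters.
#' @examples
#' resp <- generate_cortical(82.43, group_label = 0, seed = 1)
#' best_threshold(resp$table)
#' @export
generate_cortical <- function(group_mean, group_label = 0,
                              n_channels = 60, seed = NULL,
                              threshold_sd = 25, falloff = 0.55,
                              slope_uA = 15, max_spikes = 40,
                              threshold_gradient_uA_per_mm = 10,
                              currents = seq(0, 750, by = 50),
                              spacing_mm = 0.4,
                              contra_attenuation = 0.5,
                              contra_threshold_shift_uA = 30,
                              noise = c("poisson", "none"),
                              stim_electrode = 1L) {
  noise <- match.arg(noise)
  if (group_mean <= 0) stop("group_mean must be positive")
  if (n_channels < 2L) stop("need at least 2 recording channels")
  if (slope_uA <= 0) stop("sigmoid slope must be positive (monotone)")
  if (falloff < 0) stop("falloff must be non-negative")
  if (is.unsorted(currents, strictly = TRUE))
    stop("currents must be strictly increasing")
  .with_seed(seed, {
    n_ipsi <- ceiling(n_channels / 2); n_contra <- n_channels - n_ipsi
    grid <- function(n, hemi) {
      ncol_g <- ceiling(sqrt(n))
      i <- seq_len(n) - 1L
      data.frame(channel = paste0(hemi, "-", seq_len(n)),
                 hemisphere = hemi,
                 x_mm = (i %% ncol_g) * spacing_mm,
                 y_mm = (i %/% ncol_g) * spacing_mm)
    }
    ipsi <- grid(n_ipsi, "ipsi")
    contra <- grid(n_contra, "contra")
    # best site: ipsilateral channel nearest the array centre
    cen <- c(mean(ipsi$x_mm), mean(ipsi$y_mm))
    best <- which.min((ipsi$x_mm - cen[1])^2 + (ipsi$y_mm - cen[2])^2)
    t_true <- max(10, stats::rnorm(1, group_mean, threshold_sd))
    mk_counts <- function(ch, t, m_best) {
      d <- sqrt((ch$x_mm - ch$x_mm[attr(ch, "best")])^2 +
                  (ch$y_mm - ch$y_mm[attr(ch, "best")])^2)
      M <- m_best * pmax(0, 1 - falloff * d)
      t_ch <- t + threshold_gradient_uA_per_mm * d
      do.call(rbind, lapply(seq_len(nrow(ch)), function(i) {
        mu <- M[i] * stats::plogis((currents - t_ch[i]) / slope_uA)
        spikes <- if (noise == "poisson") stats::rpois(length(mu), mu)
        else mu
        data.frame(stim_electrode = stim_electrode,
                   channel = ch$channel[i],
                   hemisphere = ch$hemisphere[i],
                   x_mm = ch$x_mm[i], y_mm = ch$y_mm[i],
                   current_uA = currents, spikes = spikes)
      }))
    }
    attr(ipsi, "best") <- best
    cen_c <- c(mean(contra$x_mm), mean(contra$y_mm))
    attr(contra, "best") <- if (n_contra)
      which.min((contra$x_mm - cen_c[1])^2 + (contra$y_mm - cen_c[2])^2)
    else integer(0)
    tab <- mk_counts(ipsi, t_true, max_spikes)
    if (n_contra >= 1L)
      tab <- rbind(tab, mk_counts(contra,
                                  t_true + contra_threshold_shift_uA,
                                  max_spikes * contra_attenuation))
    structure(list(table = tab,
                   truth = list(threshold_uA = t_true, d_prime = falloff,
                                best_channel = ipsi$channel[best],
                                group = group_label),
                   group_mean = group_mean, falloff = falloff,
                   slope_uA = slope_uA, noise = noise),
              class = "cortical_response")
  })
}

#' @export
print.cortical_response <- function(x, ...) {
  cat(sprintf(
    "Cortical response (group %s): %d channels x %d currents; true threshold %.1f uA, true d' %.2f/mm\n",
    x$truth$group, length(unique(x$table$channel)),
    length(unique(x$table$current_uA)), x$truth$threshold_uA,
    x$truth$d_prime))
  invisible(x)
}

#' Generate a battery of stimulating electrodes across groups
#'
#' One [generate_cortical()] call per electrode, with group-specific true
#' mean thresholds. Defaults are the study's per-group means.
#'
#' @param n_per_group Electrodes per group.
#' @param group_means Named numeric vector of true mean best thresholds
#'   (uA) for groups 0-4.
#' @param seed RNG seed or NULL (electrode seeds derived from it).
#' @param ... Passed on to [generate_cortical()].
#' @return List with `responses` (list of `cortical_response`) and
#'   `electrodes` (data frame: `stim_electrode`, `group`,
#'   `true_threshold_uA`, `true_d_prime`).
#' @export
generate_cortical_battery <- function(n_per_group = 10,
                                      group_means = c(`0` = 82.43,
                                                      `1` = 88.64,
                                                      `2` = 98.25,
                                                      `3` = 117.25,
                                                      `4` = 124.26),
                                      seed = NULL, ...) {
  .with_seed(seed, {
    groups <- rep(as.integer(names(group_means)), each = n_per_group)
    responses <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      responses[[i]] <- generate_cortical(
        group_means[[as.character(groups[i])]],
        group_label = groups[i], seed = NULL,
        stim_electrode = i, ...)
    }
    electrodes <- data.frame(
      stim_electrode = seq_along(groups), group = groups,
      true_threshold_uA = vapply(responses,
                                 function(r) r$truth$threshold_uA,
                                 numeric(1)),
      true_d_prime = vapply(responses, function(r) r$truth$d_prime,
                            numeric(1)))
    list(responses = responses, electrodes = electrodes)
  })
}
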
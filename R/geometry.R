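# Layer geometry: boundary profiles, region segmentation, ORr sampling.
#
# Depth convention: depth 0 at the vitread (ILM) side, increasing toward the
# sclera; in images row 1 is the vitread side and columns run along the
# section.

#' Anatomical layer and boundary names
#'
#' Layers from the vitread (inner) side to the sclerad (outer) side, and the
#' boundary curves that delimit them. The outer retina (OR) comprises the
#' outer plexiform layer, outer nuclear layer, inner segments and outer
#' segments; the Outer Retina ratio (ORr) is OR thickness divided by total
#' retinal thickness (ILM surface to outer-segment edge).
#'
#' @format `orr_layers` and `orr_boundaries` are character vectors.
#' @name orr_layers
#' @export
orr_layers <- c("GCL", "IPL", "INL", "OPL", "ONL", "IS", "OS")

#' @rdname orr_layers
#' @export
orr_boundaries <- c("ILM", "GCL_IPL", "IPL_INL", "INL_OPL",
                    "OPL_ONL", "ONL_IS", "IS_OS", "OS_EDGE")

# layers forming the outer retina (numerator of ORr)
.outer_layers <- c("OPL", "ONL", "IS", "OS")

#' Construct a layer profile from boundary depth curves
#'
#' A layer profile holds the depth (in microns from the vitread surface) of
#' each of the eight anatomical boundaries as a function of lateral position
#' along the section. Depths between knots are linearly interpolated.
#'
#' @param x Numeric vector of lateral positions (micron), strictly increasing.
#' @param depths Numeric matrix with `length(x)` rows and one column per
#'   boundary, named as in [orr_boundaries]. Depths must be non-decreasing
#'   across boundaries at every `x` (non-crossing).
#' @param px_per_um Optional pixel calibration carried along for provenance.
#' @return An object of class `layer_profile`.
#' @examples
#' prof <- flat_profile(c(OS = 20, IS = 20, ONL = 40, OPL = 20,
#'                        INL = 30, IPL = 50, GCL = 20), extent_um = 1000)
#' layer_thicknesses(prof, 500)
#' @export
layer_profile <- function(x, depths, px_per_um = NULL) {
  x <- as.numeric(x)
  if (length(x) < 2L || is.unsorted(x, strictly = TRUE))
    stop("`x` must be a strictly increasing vector of at least 2 positions")
  depths <- as.matrix(depths)
  if (nrow(depths) != length(x))
    stop("`depths` must have one row per element of `x`")
  if (is.null(colnames(depths)))
    colnames(depths) <- orr_boundaries
  missing <- setdiff(orr_boundaries, colnames(depths))
  if (length(missing))
    stop("missing boundary curves: ", paste(missing, collapse = ", "))
  depths <- depths[, orr_boundaries, drop = FALSE]
  cross <- which(apply(depths, 1L, function(d) any(diff(d) < -1e-9)))
  if (length(cross))
    stop("boundaries cross (anatomical order violated) at x = ",
         paste(utils::head(signif(x[cross], 6), 5L), collapse = ", "))
  structure(list(x = x, depths = depths,
                 extent = range(x), px_per_um = px_per_um),
            class = "layer_profile")
}

#' @export
print.layer_profile <- function(x, ...) {
  cat("Layer profile:", length(x$x), "knots over [",
      format(x$extent[1]), ",", format(x$extent[2]), "] um\n")
  th <- layer_thicknesses(x, mean(x$extent))
  cat("Mid-section thicknesses (um):\n")
  print(round(th, 2))
  invisible(x)
}

#' Build a laterally uniform layer profile
#'
#' Convenience constructor for a profile with constant layer thicknesses,
#' used throughout the tests and examples.
#'
#' @param thicknesses Named numeric vector of layer thicknesses in micron;
#'   names from [orr_layers] (missing layers default to 0).
#' @param extent_um Lateral extent of the section (micron).
#' @param ilm_depth_um Depth of the ILM surface (micron), default 0.
#' @return A `layer_profile`.
#' @export
flat_profile <- function(thicknesses, extent_um, ilm_depth_um = 0) {
  th <- stats::setNames(numeric(length(orr_layers)), orr_layers)
  if (!all(names(thicknesses) %in% orr_layers))
    stop("unknown layer names: ",
         paste(setdiff(names(thicknesses), orr_layers), collapse = ", "))
  th[names(thicknesses)] <- thicknesses
  d <- cumsum(c(ILM = ilm_depth_um, th))
  names(d) <- orr_boundaries
  x <- c(0, extent_um)
  layer_profile(x, matrix(rep(d, each = 2L), nrow = 2L,
                          dimnames = list(NULL, orr_boundaries)))
}

.boundary_depths <- function(profile, x) {
  if (any(x < profile$extent[1] - 1e-9 | x > profile$extent[2] + 1e-9))
    stop("lateral position outside profile extent [",
         profile$extent[1], ", ", profile$extent[2], "] um")
  vapply(orr_boundaries, function(b)
    stats::approx(profile$x, profile$depths[, b], xout = x,
                  rule = 2L)$y, numeric(length(x)))
}

#' Layer thicknesses at a lateral position
#'
#' Thickness of each layer measured along the image column (vertical), plus
#' the outer-retina thickness (OPL + ONL + IS + OS), the total retinal
#' thickness (ILM surface to outer-segment edge) and their ratio, the ORr.
#'
#' @param profile A [layer_profile].
#' @param x Lateral position(s) in micron, inside the profile extent.
#' @return For scalar `x` a named numeric vector with elements
#'   `GCL, IPL, INL, OPL, ONL, IS, OS, OR, total, orr`; for vector `x` a
#'   matrix with one row per position.
#' @export
layer_thicknesses <- function(profile, x) {
  stopifnot(inherits(profile, "layer_profile"))
  d <- .boundary_depths(profile, x)
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L,
                                   dimnames = list(NULL, orr_boundaries))
  th <- d[, -1L, drop = FALSE] - d[, -ncol(d), drop = FALSE]
  colnames(th) <- orr_layers
  if (any(th < -1e-9))
    stop("negative layer thickness: boundaries cross")
  or <- rowSums(th[, .outer_layers, drop = FALSE])
  total <- d[, "OS_EDGE"] - d[, "ILM"]
  orr <- ifelse(total > 0, or / total, NA_real_)
  out <- cbind(th, OR = or, total = total, orr = orr)
  if (length(x) == 1L) out[1L, ] else out
}

#' Split a section into adjacent analysis regions
#'
#' Regions are adjacent, non-overlapping windows of fixed length (default
#' 250 micron) left-aligned to the start of the section; a trailing
#' remainder shorter than one region is discarded (and reported via the
#' `dropped_um` attribute).
#'
#' @param profile A [layer_profile], or a numeric extent `c(x_min, x_max)`.
#' @param region_length_um Window length in micron (default 250).
#' @return A data frame with columns `region_id`, `x_start_um`, `x_end_um`;
#'   attribute `dropped_um` holds the discarded remainder length.
#' @export
segment_regions <- function(profile, region_length_um = 250) {
  ext <- if (inherits(profile, "layer_profile")) profile$extent
         else range(as.numeric(profile))
  stopifnot(region_length_um > 0)
  span <- diff(ext)
  n <- floor(span / region_length_um + 1e-9)
  if (n < 1L)
    stop("section extent (", span, " um) shorter than one region (",
         region_length_um, " um)")
  x0 <- ext[1] + (seq_len(n) - 1L) * region_length_um
  out <- data.frame(region_id = seq_len(n), x_start_um = x0,
                    x_end_um = x0 + region_length_um)
  attr(out, "dropped_um") <- span - n * region_length_um
  out
}

#' ORr of one region from interval-midpoint samples
#'
#' ORr is sampled at the midpoints of consecutive sampling intervals inside
#' the region (for the defaults, 5 samples at 25, 75, 125, 175 and 225
#' micron past the region start) and averaged. Midpoint placement means
#' adjacent regions never share a sample; fence-post sampling is available
#' via `scheme = "fencepost"`.
#'
#' A region is flagged unmeasurable when any sample has zero total
#' thickness (severe degeneration obscuring layer delineation); its mean is
#' `NA` and it is excluded from group statistics downstream.
#'
#' @param profile A [layer_profile].
#' @param x_start_um Region start (micron); the window
#'   `[x_start_um, x_start_um + region_length_um)` must lie inside the
#'   profile extent.
#' @param region_length_um,interval_um Region length and sampling interval
#'   (micron); the region length must be a multiple of the interval.
#' @param scheme `"midpoint"` (default) or `"fencepost"`.
#' @return An object of class `region_measurement`: a list with
#'   `sample_x`, `sample_orr`, `mean_orr`, `sd_orr`, `measurable`,
#'   `x_start_um`, `length_um`.
#' @export
region_orr <- function(profile, x_start_um, region_length_um = 250,
                       interval_um = 50, scheme = c("midpoint", "fencepost")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(profile, "layer_profile"),
            region_length_um > 0, interval_um > 0)
  if (x_start_um < profile$extent[1] - 1e-9 ||
      x_start_um + region_length_um > profile$extent[2] + 1e-9)
    stop("region window outside profile extent")
  k <- region_length_um / interval_um
  if (abs(k - round(k)) > 1e-9)
    stop("region length must be a multiple of the sampling interval")
  k <- round(k)
  xs <- if (scheme == "midpoint")
    x_start_um + interval_um * (seq_len(k) - 0.5)
  else
    x_start_um + interval_um * (0:k)
  th <- layer_thicknesses(profile, xs)
  measurable <- all(th[, "total"] > 0)
  orr <- th[, "orr"]
  structure(list(sample_x = xs, sample_orr = orr,
                 mean_orr = if (measurable) mean(orr) else NA_real_,
                 sd_orr = if (measurable) stats::sd(orr) else NA_real_,
                 measurable = measurable,
                 x_start_um = x_start_um, length_um = region_length_um),
            class = "region_measurement")
}

#' @export
print.region_measurement <- function(x, ...) {
  cat(sprintf("Region [%g, %g) um: ", x$x_start_um,
              x$x_start_um + x$length_um))
  if (x$measurable)
    cat(sprintf("mean ORr %.3f (sd %.3f, %d samples)\n",
                x$mean_orr, x$sd_orr, length(x$sample_orr)))
  else cat("unmeasurable (zero total thickness at a sample)\n")
  invisible(x)
}

#' Measure all regions of a section
#'
#' Runs [segment_regions()] and [region_orr()] over a whole profile and
#' returns the tidy region table used by the grading and statistics stages.
#'
#' @inheritParams region_orr
#' @param eye_id,condition,electrode_id,in_pocket Metadata carried into the
#'   table. `condition` is `"control"` or `"treated"`; `electrode_id` may be
#'   a vector with one entry per region (NA where no electrode).
#' @return Data frame with one row per region: `eye_id`, `condition`,
#'   `region_id`, `x_start_um`, `mean_orr`, `sd_orr`, `measurable`,
#'   `electrode_id`, `in_pocket`.
#' @export
measure_regions <- function(profile, eye_id = "eye1",
                            condition = c("control", "treated"),
                            region_length_um = 250, interval_um = 50,
                            electrode_id = NA, in_pocket = FALSE,
                            scheme = c("midpoint", "fencepost")) {
  condition <- match.arg(condition)
  scheme <- match.arg(scheme)
  win <- segment_regions(profile, region_length_um)
  ms <- lapply(win$x_start_um, function(x0)
    region_orr(profile, x0, region_length_um, interval_um, scheme))
  data.frame(
    eye_id = eye_id, condition = condition,
    region_id = win$region_id, x_start_um = win$x_start_um,
    mean_orr = vapply(ms, `[[`, numeric(1), "mean_orr"),
    sd_orr = vapply(ms, `[[`, numeric(1), "sd_orr"),
    measurable = vapply(ms, `[[`, logical(1), "measurable"),
    electrode_id = rep_len(electrode_id, nrow(win)),
    in_pocket = rep_len(in_pocket, nrow(win)))
}

#' Recover boundary curves from an integer label mask
#'
#' Converts a per-pixel layer labelling (rows = depth, vitread side at row
#' 1; columns = lateral position) into boundary depth curves by a
#' per-column extremal scan. Labels follow [orr_layers] order: 1 = GCL ...
#' 7 = OS, 0 = background. A layer absent in a column gets zero thickness
#' there (its boundaries coincide).
#'
#' @param mask Integer matrix of layer labels.
#' @param px_per_um Pixels per micron calibration (> 0).
#' @return A [layer_profile] with one knot per image column.
#' @export
profile_from_mask <- function(mask, px_per_um) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix of integer labels")
  if (!is.numeric(px_per_um) || length(px_per_um) != 1L || px_per_um <= 0)
    stop("`px_per_um` must be a positive scalar")
  nl <- length(orr_layers)
  cols <- which(colSums(mask > 0L) > 0L)
  if (length(cols) < 2L) stop("mask contains fewer than 2 labelled columns")
  depths <- matrix(NA_real_, length(cols), nl + 1L,
                   dimnames = list(NULL, orr_boundaries))
  for (j in seq_along(cols)) {
    v <- mask[, cols[j]]
    # top edge of the first labelled pixel, then bottom edge of each layer
    first <- which(v > 0L)[1L]
    d <- (first - 1L) / px_per_um
    depths[j, 1L] <- d
    for (k in seq_len(nl)) {
      rows <- which(v == k)
      if (length(rows)) d <- max(rows) / px_per_um
      depths[j, k + 1L] <- d
    }
  }
  # knots at column centres, padded to the outer pixel edges so the
  # extent covers the full labelled width
  x <- c((cols[1] - 1L) / px_per_um, (cols - 0.5) / px_per_um,
         cols[length(cols)] / px_per_um)
  depths <- rbind(depths[1L, ], depths, depths[nrow(depths), ])
  layer_profile(x, depths, px_per_um = px_per_um)
}
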
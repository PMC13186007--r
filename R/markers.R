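# Marker quantification: background-subtracted fluorescence intensity,
# DAPI nuclei counting with watershed splitting, opsin-positive nuclei,
# and DAB positive-pixel area by colour deconvolution.
#
# Image convention: numeric matrices in [0, 1], rows = depth (vitread side
# at row 1), columns = lateral position; RGB images are H x W x 3 arrays.

#' Background-subtracted fluorescence intensity
#'
#' Mean marker intensity over a target mask minus the mean over a choroid
#' (background) mask. Negative values (signal below background) are
#' retained, not clamped, and flagged via the `below_background` attribute
#' so distributional statistics remain unbiased.
#'
#' @param image Numeric matrix (single fluorescence channel).
#' @param target_mask,choroid_mask Logical matrices, non-empty and
#'   disjoint, same dimensions as `image`.
#' @return Background-subtracted mean intensity (attribute
#'   `below_background` when negative).
#' @export
fluorescence_intensity <- function(image, target_mask, choroid_mask) {
  stopifnot(is.matrix(image),
            identical(dim(image), dim(target_mask)),
            identical(dim(image), dim(choroid_mask)))
  target_mask <- target_mask > 0; choroid_mask <- choroid_mask > 0
  if (!any(target_mask)) stop("empty target mask")
  if (!any(choroid_mask)) stop("empty choroid mask")
  if (any(target_mask & choroid_mask))
    stop("target and choroid masks overlap")
  out <- mean(image[target_mask]) - mean(image[choroid_mask])
  if (out < 0) attr(out, "below_background") <- TRUE
  out
}

#' Normalize an intensity to same-animal control images
#'
#' Divides a background-subtracted intensity by the mean of the
#' background-subtracted intensities of all control-eye images of the same
#' animal and marker. Subtracting background before averaging makes the
#' normalization invariant to constant illumination offsets.
#'
#' @param value Background-subtracted intensity to normalize.
#' @param control_values Background-subtracted control intensities.
#' @return `value / mean(control_values)`.
#' @export
normalize_to_control <- function(value, control_values) {
  m <- mean(control_values, na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("control mean must be positive (got ", format(m), ")")
  as.numeric(value) / m
}

#' Count nuclei in a layer band
#'
#' Replicates the particle-analysis workflow: automatic (Otsu) intensity
#' threshold on the masked DAPI channel, distance-transform watershed
#' splitting of touching nuclei, then filtering of connected components by
#' area and circularity (`4 * pi * area / perimeter^2`). The defaults
#' (min_area 0, circularity [0, 1]) impose no shape filtering, so the count
#' equals the raw post-watershed component count. Counts are normalized by
#' the lateral extent of the mask in mm.
#'
#' @param image Numeric matrix in [0, 1] (DAPI channel).
#' @param layer_mask Logical matrix, non-empty; the band to count in.
#' @param px_per_um Pixels per micron (> 0).
#' @param min_area_um2 Minimum component area (micron^2), default 0.
#' @param circularity Length-2 inclusive window on circularity; an upper
#'   bound >= 1 disables the upper cut (discretization can push measured
#'   circularity slightly above 1).
#' @param threshold Optional fixed intensity threshold; default Otsu on the
#'   pixels inside the mask.
#' @param tolerance Watershed tolerance (minimum distance-map height
#'   separating two objects), default 0.5 px: splits touching ~4 micron
#'   nuclei while leaving isolated ones intact.
#' @return Object of class `nucleus_set`: list with `labels` (integer
#'   matrix), `stats` (data frame: label, x_um, depth_um, area_um2,
#'   circularity), `count`, `count_per_mm`, `threshold`,
#'   `low_confidence`.
#' @export
count_nuclei <- function(image, layer_mask, px_per_um,
                         min_area_um2 = 0, circularity = c(0, 1),
                         threshold = NULL, tolerance = 0.5) {
  stopifnot(is.matrix(image), identical(dim(image), dim(layer_mask)),
            px_per_um > 0)
  layer_mask <- layer_mask > 0
  if (!any(layer_mask)) stop("empty layer mask")
  vals <- image[layer_mask]
  low_confidence <- FALSE
  if (is.null(threshold)) {
    if (diff(range(vals)) < 1e-8) {
      # saturated or empty band: thresholding has no information
      threshold <- if (vals[1] > 0) vals[1] - 1e-6 else Inf
      low_confidence <- TRUE
    } else {
      threshold <- EBImage::otsu(matrix(vals, nrow = 1L),
                                 range = range(vals))
    }
  }
  binary <- (image > threshold) & layer_mask
  if (!any(binary)) {
    empty <- list(labels = matrix(0L, nrow(image), ncol(image)),
                  stats = data.frame(label = integer(), x_um = numeric(),
                                     depth_um = numeric(),
                                     area_um2 = numeric(),
                                     circularity = numeric()),
                  count = 0L,
                  count_per_mm = 0,
                  threshold = threshold, low_confidence = low_confidence)
    class(empty) <- "nucleus_set"
    return(empty)
  }
  dm <- EBImage::distmap(EBImage::Image(binary * 1))
  labels <- EBImage::watershed(dm, tolerance = tolerance)
  labels <- EBImage::imageData(labels)
  shp <- EBImage::computeFeatures.shape(labels)
  area_um2 <- shp[, "s.area"] / px_per_um^2
  circ <- 4 * pi * shp[, "s.area"] / pmax(shp[, "s.perimeter"], 1e-9)^2
  # centroids from the label matrix (row = depth, col = lateral)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  cen_row <- tapply(idx[, 1L], lab, mean)
  cen_col <- tapply(idx[, 2L], lab, mean)
  keep <- area_um2 >= min_area_um2 & circ >= circularity[1]
  if (circularity[2] < 1) keep <- keep & circ <= circularity[2]
  stats_df <- data.frame(
    label = seq_len(nrow(shp)),
    x_um = as.numeric(cen_col) / px_per_um,
    depth_um = as.numeric(cen_row) / px_per_um,
    area_um2 = as.numeric(area_um2),
    circularity = as.numeric(circ))[keep, , drop = FALSE]
  labels[!(labels %in% stats_df$label)] <- 0L
  cols <- range(which(colSums(layer_mask) > 0))
  length_mm <- (cols[2] - cols[1] + 1) / px_per_um / 1000
  out <- list(labels = labels, stats = stats_df,
              count = nrow(stats_df),
              count_per_mm = nrow(stats_df) / length_mm,
              threshold = threshold, low_confidence = low_confidence)
  class(out) <- "nucleus_set"
  out
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("Nucleus set: %d nuclei (%.1f per mm)%s\n",
              x$count, x$count_per_mm,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Count marker-positive nuclei
#'
#' A nucleus is marker-positive when at least `overlap_fraction` of its
#' pixels exceed the intensity threshold in the co-registered marker
#' channel. This operator replaces a manual positive-nucleus count.
#'
#' @param nuclei A [count_nuclei()] result.
#' @param channel Numeric matrix, same dimensions as the nucleus labels.
#' @param intensity_threshold Positivity threshold on the channel.
#' @param overlap_fraction Minimum positive-pixel fraction (default 0.5).
#' @return Integer count; attribute `positive_labels` lists the labels.
#' @export
positive_nuclei <- function(nuclei, channel, intensity_threshold,
                            overlap_fraction = 0.5) {
  stopifnot(inherits(nuclei, "nucleus_set"),
            identical(dim(channel), dim(nuclei$labels)))
  if (intensity_threshold < min(channel) || intensity_threshold > max(channel))
    warning("intensity threshold outside channel range")
  if (nuclei$count == 0L) return(structure(0L, positive_labels = integer()))
  inside <- nuclei$labels > 0
  lab <- nuclei$labels[inside]
  pos <- channel[inside] > intensity_threshold
  frac <- tapply(pos, lab, mean)
  hits <- as.integer(names(frac)[frac >= overlap_fraction])
  structure(length(hits), positive_labels = hits)
}

# Standard H-DAB stain optical-density vectors (unit length): rows are
# haematoxylin, DAB, and a residual completing the basis.
.hdab_stains <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  rbind(H = h / sqrt(sum(h^2)), DAB = d / sqrt(sum(d^2)),
        R = r / sqrt(sum(r^2)))
}

#' DAB positive-pixel area per retinal length
#'
#' Classifies pixels of an RGB brightfield image as DAB-positive (brown
#' reaction product) and returns the positive area divided by the lateral
#' length of the analysed mask, in micron^2 per micron.
#'
#' Two classification rules are available. `"deconvolution"` (default)
#' unmixes per-pixel optical densities with the standard
#' haematoxylin/DAB stain vectors and calls a pixel positive when its DAB
#' optical density exceeds `od_threshold`; haematoxylin-blue pixels have
#' zero DAB density and are excluded by construction. `"hue"` is a plain
#' HSV window on brown hues.
#'
#' @param rgb Numeric H x W x 3 array in [0, 1].
#' @param layer_mask Logical H x W matrix, non-empty.
#' @param px_per_um Pixels per micron (> 0).
#' @param method `"deconvolution"` or `"hue"`.
#' @param od_threshold DAB optical-density cut (default 0.15).
#' @param hue_range,min_saturation,max_value HSV window for the hue rule
#'   (hue fractions of a turn; DAB brown spans roughly 10-60 degrees).
#' @return Positive area per retinal length (micron^2 / micron), with the
#'   positive-pixel mask in attribute `positive`.
#' @export
dab_positive_area <- function(rgb, layer_mask, px_per_um,
                              method = c("deconvolution", "hue"),
                              od_threshold = 0.15,
                              hue_range = c(10, 60) / 360,
                              min_saturation = 0.25, max_value = 0.95) {
  method <- match.arg(method)
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("`rgb` must be an H x W x 3 array (grayscale input rejected)")
  stopifnot(identical(dim(rgb)[1:2], dim(layer_mask)), px_per_um > 0)
  layer_mask <- layer_mask > 0
  if (!any(layer_mask)) stop("empty layer mask")
  px <- cbind(r = rgb[, , 1][layer_mask],
              g = rgb[, , 2][layer_mask],
              b = rgb[, , 3][layer_mask])
  if (method == "deconvolution") {
    od <- -log10(pmax(px, 1 / 255))
    conc <- od %*% solve(.hdab_stains())
    pos <- conc[, "DAB"] > od_threshold
  } else {
    hsv <- grDevices::rgb2hsv(t(px), maxColorValue = 1)
    pos <- hsv["h", ] >= hue_range[1] & hsv["h", ] <= hue_range[2] &
      hsv["s", ] >= min_saturation & hsv["v", ] <= max_value
  }
  pos_mask <- layer_mask
  pos_mask[layer_mask] <- pos
  cols <- range(which(colSums(layer_mask) > 0))
  length_um <- (cols[2] - cols[1] + 1) / px_per_um
  area_um2 <- sum(pos) / px_per_um^2
  structure(area_um2 / length_um, positive = pos_mask)
}

#' RBPMS-positive fraction of GCL nuclei
#'
#' Ratio of retinal-ganglion-cell-marker-positive nuclei to total nuclei
#' counted in the ganglion cell layer.
#'
#' @param rbpms_positive_count,gcl_nuclei_count Non-negative counts;
#'   positives cannot exceed the total and the total must be > 0.
#' @return Ratio in [0, 1].
#' @export
rbpms_ratio <- function(rbpms_positive_count, gcl_nuclei_count) {
  if (any(gcl_nuclei_count <= 0))
    stop("ratio undefined: zero GCL nuclei")
  if (any(rbpms_positive_count < 0 |
          rbpms_positive_count > gcl_nuclei_count))
    stop("positive count must lie in [0, total]")
  rbpms_positive_count / gcl_nuclei_count
}

#' Is a region eligible for photoreceptor-marker quantification?
#'
#' Photoreceptor markers (rhodopsin, cone opsin, ONL nuclei) are not
#' analysed in severely degenerated (group 4) or unmeasurable regions,
#' where the outer retinal layers cannot be reliably delineated.
#'
#' @param group Integer group vector (NA = indeterminate).
#' @param measurable Logical vector (recycled).
#' @return Logical vector.
#' @export
photoreceptor_quantifiable <- function(group, measurable = TRUE) {
  measurable <- rep_len(measurable, length(group))
  !is.na(group) & group != 4L & measurable
}
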
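# Synthetic retinal cross-sections with ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# control region ORr ~ Normal(0.55, 0.05) truncated to [0.39, 0.69];
# treated ORr drawn from a degeneration-group mixture (spanning 0-0.64)
# with optional spatial correlation; ONL nuclei density following
# 10*log10(CD) = A + B*ORr with Gaussian dB residuals; per-group
# multiplicative marker effects and ectopic-opsin rates; a DAB channel with
# known brown chromaticity over a haematoxylin-blue background.
#
# Geometry: the inner retina (GCL+IPL+INL) has fixed thickness and the
# outer retina is scaled so that OR / total matches the target ORr field
# (total = inner / (1 - ORr)). Row 1 of every image is the vitread (ILM)
# side.

# evaluate code with a locally set RNG seed, restoring global state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic retinal section
#'
#' Collects and validates all generator parameters. Defaults are the study
#' conditions the analysis targets; see the package vignette for the
#' rationale behind each.
#'
#' @param length_um Section extent (micron), >= 250 (one region).
#' @param px_per_um Pixel calibration (> 0), default 1.
#' @param condition `"control"` or `"treated"`.
#' @param orr_field Target ORr: `NULL` (drawn per region from the
#'   condition's distribution), a numeric scalar / per-region vector, or a
#'   function of lateral position (micron). Values must lie in [0, 1).
#' @param inner_thickness_um Fixed inner-retina thickness (micron).
#' @param outer_fractions,inner_fractions Relative thicknesses of
#'   OS/IS/ONL/OPL within the outer retina and GCL/IPL/INL within the
#'   inner retina; each set sums to 1.
#' @param control_orr_mean,control_orr_sd,control_orr_range Truncated
#'   normal for control region ORr (defaults 0.55, 0.05, [0.39, 0.69]).
#' @param treated_mixture Target proportions of treated regions in groups
#'   1-4 (sums to 1); defaults to the study mixture
#'   272/220/263/79 over 834.
#' @param treated_orr_max Upper ORr bound for treated retina (0.64).
#' @param correlation_length_um Spatial correlation length (micron) of the
#'   latent Gaussian field coupling neighbouring treated regions (0 =
#'   independent regions). Default 500.
#' @param canonical_threshold Normative threshold used for ground-truth
#'   group labels (default 0.44).
#' @param nuclei_model List: `A_db`, `B_db`, `residual_sd_db` for the ONL
#'   density model; `radius_um` nucleus radius; `inl_per_mm`, `gcl_per_mm`
#'   densities of inner nuclei.
#' @param marker_effects List of per-group (0-4) vectors: `os_intensity`
#'   multiplicative rhodopsin outer-segment intensity, `ectopic_rate`
#'   fraction of ONL nuclei rendered opsin-positive, `dab_area_per_um`
#'   target DAB-positive area per length (micron^2/micron) in the IPL,
#'   `rbpms_fraction` RBPMS-positive fraction of GCL nuclei.
#' @param region_length_um,interval_um Region geometry (250 / 50 micron).
#' @param seed RNG seed (integer or NULL).
#' @return Object of class `section_spec`.
#' @export
section_spec <- function(length_um = 2000, px_per_um = 1,
                         condition = c("control", "treated"),
                         orr_field = NULL,
                         inner_thickness_um = 90,
                         outer_fractions = c(OS = 0.20, IS = 0.15,
                                             ONL = 0.50, OPL = 0.15),
                         inner_fractions = c(GCL = 0.20, IPL = 0.45,
                                             INL = 0.35),
                         control_orr_mean = 0.55, control_orr_sd = 0.05,
                         control_orr_range = c(0.39, 0.69),
                         treated_mixture = c(272, 220, 263, 79) / 834,
                         treated_orr_max = 0.64,
                         correlation_length_um = 500,
                         canonical_threshold = 0.44,
                         nuclei_model = list(A_db = 20.86, B_db = 25.56,
                                             residual_sd_db = 1.96,
                                             radius_um = 2,
                                             inl_per_mm = 420,
                                             gcl_per_mm = 60),
                         marker_effects = list(
                           os_intensity = c(1, 0.85, 0.7, 0.55, 0.25),
                           ectopic_rate = c(0.0, 0.05, 0.12, 0.2, 0.3),
                           dab_area_per_um = c(0.5, 0.6, 0.8, 1.2, 1.5),
                           rbpms_fraction = c(0.8, 0.45, 0.45, 0.45, 0.45)),
                         region_length_um = 250, interval_um = 50,
                         seed = NULL) {
  condition <- match.arg(condition)
  if (!is.numeric(px_per_um) || px_per_um <= 0)
    stop("px_per_um must be positive")
  if (length_um < region_length_um)
    stop("section must cover at least one region (", region_length_um,
         " um)")
  if (abs(sum(outer_fractions) - 1) > 1e-9 ||
      abs(sum(inner_fractions) - 1) > 1e-9)
    stop("layer fractions within each compartment must sum to 1")
  if (any(outer_fractions < 0) || any(inner_fractions < 0))
    stop("layer fractions must be non-negative")
  if (is.numeric(orr_field) &&
      any(orr_field < 0 | orr_field >= 1))
    stop("orr_field values must lie in [0, 1)")
  if (abs(sum(treated_mixture) - 1) > 1e-9 || any(treated_mixture < 0))
    stop("treated_mixture must be proportions summing to 1")
  structure(list(
    length_um = length_um, px_per_um = px_per_um, condition = condition,
    orr_field = orr_field, inner_thickness_um = inner_thickness_um,
    outer_fractions = outer_fractions[c("OS", "IS", "ONL", "OPL")],
    inner_fractions = inner_fractions[c("GCL", "IPL", "INL")],
    control_orr_mean = control_orr_mean, control_orr_sd = control_orr_sd,
    control_orr_range = control_orr_range,
    treated_mixture = treated_mixture, treated_orr_max = treated_orr_max,
    correlation_length_um = correlation_length_um,
    canonical_threshold = canonical_threshold,
    nuclei_model = nuclei_model, marker_effects = marker_effects,
    region_length_um = region_length_um, interval_um = interval_um,
    seed = seed), class = "section_spec")
}

# truncated normal draws by rejection
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# quantile function of the treated ORr mixture: groups in ascending ORr
# order (severe, moderate, mild, none), uniform within each group's range
.treated_quantile <- function(u, mixture, threshold, orr_max) {
  lo <- c(0, 0.2, 0.35, threshold)
  hi <- c(0.2, 0.35, threshold, orr_max)
  w <- rev(mixture)               # mixture is (g1, g2, g3, g4)
  cw <- cumsum(c(0, w))
  out <- numeric(length(u))
  for (k in 1:4) {
    inb <- u >= cw[k] & (u < cw[k + 1] | (k == 4 & u <= 1))
    out[inb] <- lo[k] + (u[inb] - cw[k]) / w[k] * (hi[k] - lo[k])
  }
  out
}

# draw one ORr value per region according to the spec
.draw_region_orr <- function(spec, n_regions) {
  if (spec$condition == "control")
    return(.rtruncnorm(n_regions, spec$control_orr_mean,
                       spec$control_orr_sd,
                       spec$control_orr_range[1], spec$control_orr_range[2]))
  # latent Gaussian field at region centres -> copula -> mixture quantile
  centres <- (seq_len(n_regions) - 0.5) * spec$region_length_um
  L <- spec$correlation_length_um
  z <- if (L > 0 && n_regions > 1L) {
    C <- exp(-outer(centres, centres, "-")^2 / (2 * L^2))
    ch <- chol(C + diag(1e-8, n_regions))
    drop(crossprod(ch, stats::rnorm(n_regions)))
  } else stats::rnorm(n_regions)
  u <- stats::pnorm(z)
  pmin(.treated_quantile(u, spec$treated_mixture,
                         spec$canonical_threshold, spec$treated_orr_max),
       0.999)
}

# per-pixel-column ORr values from the spec's field description
.orr_per_column <- function(spec, x_cols, n_regions) {
  f <- spec$orr_field
  if (is.function(f)) return(f(x_cols))
  if (is.numeric(f)) {
    per_region <- rep_len(f, n_regions)
  } else {
    per_region <- .draw_region_orr(spec, n_regions)
  }
  idx <- pmin(floor(x_cols / spec$region_length_um) + 1L, n_regions)
  per_region[idx]
}

# render disks into a matrix: anti-aliased (linear edge ramp) by default,
# hard-edged with `hard = TRUE`
.render_disks <- function(img, rows_px, cols_px, r_px, value = 1,
                          hard = FALSE) {
  H <- nrow(img); W <- ncol(img)
  for (i in seq_along(rows_px)) {
    r0 <- rows_px[i]; c0 <- cols_px[i]
    rr <- max(1L, floor(r0 - r_px - 1)):min(H, ceiling(r0 + r_px + 1))
    cc <- max(1L, floor(c0 - r_px - 1)):min(W, ceiling(c0 + r_px + 1))
    d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, "+"))
    v <- if (hard) (d <= r_px) * value
         else pmin(pmax(r_px + 0.5 - d, 0), 1) * value
    img[rr, cc] <- pmax(img[rr, cc], v)
  }
  img
}

# dart-throwing placement: uniform proposals in a box, accepted when at
# least min_dist from all previously accepted points
.place_points <- function(n_target, x_range, y_range, min_dist,
                          max_attempts = 15L * n_target + 50L) {
  if (n_target <= 0) return(cbind(x = numeric(0), y = numeric(0)))
  xs <- stats::runif(max_attempts, x_range[1], x_range[2])
  ys <- stats::runif(max_attempts, y_range[1], y_range[2])
  ax <- numeric(n_target); ay <- numeric(n_target); k <- 0L
  for (i in seq_len(max_attempts)) {
    if (k >= n_target) break
    if (k > 0L) {
      if (min((xs[i] - ax[1:k])^2 + (ys[i] - ay[1:k])^2) < min_dist^2)
        next
    }
    k <- k + 1L
    ax[k] <- xs[i]; ay[k] <- ys[i]
  }
  cbind(x = ax[seq_len(k)], y = ay[seq_len(k)])
}

#' Generate a synthetic retinal section with ground truth
#'
#' Renders a multi-channel image stack (structural, DAPI, fluorescent
#' marker, DAB RGB) plus an integer layer label mask, together with the
#' full ground truth: the layer-boundary profile, per-region true ORr and
#' group, nucleus centres per layer, and per-region true marker values.
#' Deterministic for a fixed spec and seed.
#'
#' @param spec A [section_spec()].
#' @param render Render images and place nuclei (default TRUE)? With
#'   FALSE only the ground truth (profile, region table) is produced --
#'   the fast path for large-n statistical checks; `images`,
#'   `label_mask` and `nuclei` are then NULL/empty.
#' @return Object of class `synthetic_section`: list with `images` (list
#'   `structure`, `dapi`, `marker` matrices and `dab` H x W x 3 array, all
#'   in [0, 1]), `label_mask` (integer matrix, 0 background, 1-7 the
#'   layers in [orr_layers] order), `truth` (list: `profile`, `regions`
#'   data frame, `nuclei` data frame, `choroid_mask`), and `spec`.
#' @examples
#' sec <- generate_section(section_spec(length_um = 500, seed = 1))
#' sec$truth$regions
#' @export
generate_section <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "section_spec"))
  .with_seed(spec$seed, {
    px <- spec$px_per_um
    W <- round(spec$length_um * px)
    x_cols <- (seq_len(W) - 0.5) / px
    n_regions <- floor(spec$length_um / spec$region_length_um)
    orr_x <- .orr_per_column(spec, x_cols, n_regions)
    if (any(orr_x < 0 | orr_x >= 1)) stop("ORr field outside [0, 1)")

    inner <- spec$inner_thickness_um
    total_x <- inner / (1 - orr_x)
    outer_x <- total_x - inner
    margin_top <- 10; choroid_um <- 25; margin_bot <- 10

    # boundary depths per column, vitread to sclerad
    layer_th <- cbind(
      GCL = inner * spec$inner_fractions[["GCL"]],
      IPL = inner * spec$inner_fractions[["IPL"]],
      INL = inner * spec$inner_fractions[["INL"]],
      OPL = outer_x * spec$outer_fractions[["OPL"]],
      ONL = outer_x * spec$outer_fractions[["ONL"]],
      IS = outer_x * spec$outer_fractions[["IS"]],
      OS = outer_x * spec$outer_fractions[["OS"]])
    depths <- cbind(ILM = rep(margin_top, W),
                    margin_top + t(apply(layer_th, 1L, cumsum)))
    colnames(depths) <- orr_boundaries
    profile <- layer_profile(x_cols, depths, px_per_um = px)

    # region ground truth (ORr at interval midpoints of the field)
    k <- spec$region_length_um / spec$interval_um
    regions <- data.frame(region_id = seq_len(n_regions))
    regions$x_start_um <- (regions$region_id - 1L) * spec$region_length_um
    mid <- function(x0) x0 + spec$interval_um * (seq_len(k) - 0.5)
    field_at <- stats::approxfun(x_cols, orr_x, rule = 2L)
    regions$orr_true <- vapply(regions$x_start_um,
                               function(x0) mean(field_at(mid(x0))),
                               numeric(1))
    regions$group_true <- classify_region(
      regions$orr_true, ifelse(spec$condition == "control",
                               "control", "treated"),
      structure(list(mu = NA, sigma = NA,
                     threshold = spec$canonical_threshold,
                     sd_multiplier = 2, n = 0L),
                class = "orr_normative"))

    # nuclei: ONL density from the log-linear model, INL/GCL at fixed rates
    nm <- spec$nuclei_model
    me <- spec$marker_effects
    reg_len_mm <- spec$region_length_um / 1000
    eps <- stats::rnorm(n_regions, 0, nm$residual_sd_db)
    regions$onl_density_true <- 10^((nm$A_db + nm$B_db * regions$orr_true +
                                       eps) / 10)
    regions$onl_target_count <- stats::rpois(n_regions,
                                             regions$onl_density_true *
                                               reg_len_mm)
    gidx <- regions$group_true + 1L
    regions$os_intensity_true <- me$os_intensity[gidx]
    regions$ectopic_rate_true <- me$ectopic_rate[gidx]
    regions$dab_area_per_um_target <- me$dab_area_per_um[gidx]
    regions$rbpms_fraction_true <- me$rbpms_fraction[gidx]
    if (!render) {
      return(structure(list(
        images = NULL, label_mask = NULL,
        truth = list(profile = profile, regions = regions,
                     nuclei = data.frame(), choroid_mask = NULL,
                     orr_columns = orr_x),
        spec = spec), class = "synthetic_section"))
    }

    H <- ceiling((margin_top + max(total_x) + choroid_um + margin_bot) * px)
    depth_rows <- (seq_len(H) - 0.5) / px

    # label mask: per column, find the layer band containing each row
    label_mask <- matrix(0L, H, W)
    for (j in seq_len(W)) {
      b <- depths[j, ]
      lab <- findInterval(depth_rows, b)   # 0 above ILM, 8 below OS edge
      lab[lab == 8L] <- 0L
      label_mask[, j] <- lab
    }
    choroid_mask <- matrix(FALSE, H, W)
    for (j in seq_len(W)) {
      lo <- depths[j, "OS_EDGE"]
      choroid_mask[, j] <- depth_rows >= lo & depth_rows < lo + choroid_um
    }

    nuclei <- list()
    for (i in seq_len(n_regions)) {
      x0 <- regions$x_start_um[i]; x1 <- x0 + spec$region_length_um
      jj <- which(x_cols >= x0 & x_cols < x1)
      gband <- function(top, bot)
        c(mean(depths[jj, top]), mean(depths[jj, bot]))
      place_band <- function(n, top, bot, layer) {
        b <- gband(top, bot)
        if (diff(b) < 2 * nm$radius_um * 0.5 || n <= 0)
          return(NULL)
        pts <- .place_points(n, c(x0, x1),
                             c(b[1] + nm$radius_um * 0.5,
                               b[2] - nm$radius_um * 0.5),
                             min_dist = 1.8 * nm$radius_um)
        if (!nrow(pts)) return(NULL)
        data.frame(region_id = i, layer = layer,
                   x_um = pts[, "x"], depth_um = pts[, "y"],
                   ectopic = FALSE, rbpms = FALSE)
      }
      g <- regions$group_true[i] + 1L
      onl <- place_band(regions$onl_target_count[i], "OPL_ONL", "ONL_IS",
                        "ONL")
      if (!is.null(onl) && nrow(onl) > 0) {
        n_ect <- stats::rbinom(1L, nrow(onl), me$ectopic_rate[g])
        if (n_ect > 0)
          onl$ectopic[sample.int(nrow(onl), n_ect)] <- TRUE
      }
      inl <- place_band(stats::rpois(1L, nm$inl_per_mm * reg_len_mm),
                        "IPL_INL", "INL_OPL", "INL")
      gcl <- place_band(stats::rpois(1L, nm$gcl_per_mm * reg_len_mm),
                        "ILM", "GCL_IPL", "GCL")
      if (!is.null(gcl) && nrow(gcl) > 0) {
        n_pos <- stats::rbinom(1L, nrow(gcl), me$rbpms_fraction[g])
        if (n_pos > 0)
          gcl$rbpms[sample.int(nrow(gcl), n_pos)] <- TRUE
      }
      nuclei[[i]] <- rbind(onl, inl, gcl)
    }
    nuclei <- do.call(rbind, nuclei)
    if (is.null(nuclei))
      nuclei <- data.frame(region_id = integer(), layer = character(),
                           x_um = numeric(), depth_um = numeric(),
                           ectopic = logical(), rbpms = logical())
    regions$onl_rendered_count <- vapply(regions$region_id, function(i)
      sum(nuclei$region_id == i & nuclei$layer == "ONL"), integer(1))
    regions$onl_rendered_per_mm <- regions$onl_rendered_count / reg_len_mm

    r_px <- nm$radius_um * px
    nrow_px <- nuclei$depth_um * px + 0.5
    ncol_px <- nuclei$x_um * px + 0.5

    # DAPI: all nuclei as bright disks
    dapi <- matrix(0, H, W)
    dapi <- .render_disks(dapi, nrow_px, ncol_px, r_px, value = 0.9)

    # fluorescent marker (rhodopsin-like): outer segments at a per-group
    # intensity, choroid autofluorescence background, ectopic ONL nuclei
    marker <- matrix(0.02, H, W)
    os_base <- 0.6
    g_of_col <- regions$group_true[
      pmin(floor(x_cols / spec$region_length_um) + 1L, n_regions)]
    for (j in seq_len(W)) {
      os_rows <- depth_rows >= depths[j, "IS_OS"] &
        depth_rows < depths[j, "OS_EDGE"]
      marker[os_rows, j] <- os_base * me$os_intensity[g_of_col[j] + 1L]
    }
    marker[choroid_mask] <- 0.08
    ect <- nuclei$layer == "ONL" & nuclei$ectopic
    if (any(ect))
      marker <- .render_disks(marker, nrow_px[ect], ncol_px[ect], r_px,
                              value = 0.75)

    # structural channel: per-layer grey levels plus dark nuclei
    grey <- c("0" = 0.95, "1" = 0.75, "2" = 0.85, "3" = 0.65,
              "4" = 0.85, "5" = 0.55, "6" = 0.80, "7" = 0.70)
    structure_ch <- matrix(grey[as.character(label_mask)], H, W)
    structure_ch[choroid_mask] <- 0.5
    nuc_img <- .render_disks(matrix(0, H, W), nrow_px, ncol_px, r_px)
    structure_ch <- structure_ch * (1 - 0.5 * nuc_img)

    # DAB RGB via Beer-Lambert with fixed stain chromaticities:
    # haematoxylin on nuclei, DAB (brown) blobs in the IPL with a
    # per-group target area
    stains <- .hdab_stains()
    conc_h <- 0.8 * nuc_img
    conc_d <- matrix(0, H, W)
    dab_r_um <- 2
    regions$dab_area_true_um2 <- 0
    for (i in seq_len(n_regions)) {
      x0 <- regions$x_start_um[i]; x1 <- x0 + spec$region_length_um
      jj <- which(x_cols >= x0 & x_cols < x1)
      band <- c(mean(depths[jj, "GCL_IPL"]), mean(depths[jj, "IPL_INL"]))
      target_area <- me$dab_area_per_um[regions$group_true[i] + 1L] *
        spec$region_length_um
      n_blob <- round(target_area / (pi * dab_r_um^2))
      pts <- .place_points(n_blob, c(x0, x1),
                           c(band[1] + dab_r_um, band[2] - dab_r_um),
                           min_dist = 2.2 * dab_r_um)
      if (nrow(pts))
        conc_d <- .render_disks(conc_d, pts[, "y"] * px + 0.5,
                                pts[, "x"] * px + 0.5, dab_r_um * px,
                                value = 0.9, hard = TRUE)
      regions$dab_area_true_um2[i] <- sum(conc_d[, jj] > 0) / px^2
    }
    dab <- array(0, c(H, W, 3))
    for (ch in 1:3)
      dab[, , ch] <- 10^-(conc_h * stains["H", ch] +
                            conc_d * stains["DAB", ch])

    structure(list(
      images = list(structure = structure_ch, dapi = dapi,
                    marker = marker, dab = dab),
      label_mask = label_mask,
      truth = list(profile = profile, regions = regions, nuclei = nuclei,
                   choroid_mask = choroid_mask, orr_columns = orr_x),
      spec = spec), class = "synthetic_section")
  })
}

#' @export
print.synthetic_section <- function(x, ...) {
  r <- x$truth$regions
  cat(sprintf(
    "Synthetic %s section: %g um (%d regions), %d x %d px\n",
    x$spec$condition, x$spec$length_um, nrow(r), nrow(x$images$dapi),
    ncol(x$images$dapi)))
  cat(sprintf("  true ORr %.2f-%.2f; %d nuclei rendered\n",
              min(r$orr_true), max(r$orr_true), nrow(x$truth$nuclei)))
  invisible(x)
}

#' Simulate (ORr, ONL density) pairs from the log-linear model
#'
#' Draws ORr from a clamped normal and densities from
#' `10^((A + B*orr + e)/10)` with Gaussian dB residuals; the direct route
#' for density-model parameter-recovery checks without image rendering.
#'
#' @param n Number of regions.
#' @param A,B,sd_db Model parameters (dB scale).
#' @param orr_mean,orr_sd Distribution of ORr values (clamped to [0, 1]).
#' @param seed RNG seed or NULL.
#' @return Data frame with columns `orr`, `density`.
#' @export
simulate_onl_density <- function(n, A = 20.86, B = 25.56, sd_db = 1.96,
                                 orr_mean = 0.45, orr_sd = 0.1,
                                 seed = NULL) {
  .with_seed(seed, {
    orr <- pmin(pmax(stats::rnorm(n, orr_mean, orr_sd), 0), 1)
    data.frame(orr = orr,
               density = 10^((A + B * orr +
                                stats::rnorm(n, 0, sd_db)) / 10))
  })
}

#' Write a synthetic section to disk
#'
#' Writes the channel stack as a multi-page TIFF (structure, DAPI, marker,
#' label mask scaled by 1/7, then the three DAB planes), the region ground
#' truth as CSV, and the scene parameters as JSON.
#'
#' @param section A [generate_section()] result.
#' @param dir Output directory (created if needed).
#' @param stem File stem, default `"section"`.
#' @return Invisibly, the paths written.
#' @export
write_section <- function(section, dir, stem = "section") {
  stopifnot(inherits(section, "synthetic_section"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(stem, ".tiff"))
  img <- section$images
  pages <- list(img$structure, img$dapi, img$marker,
                section$label_mask / 7,
                img$dab[, , 1], img$dab[, , 2], img$dab[, , 3])
  tiff::writeTIFF(pages, tif, bits.per.sample = 16L)
  csv <- file.path(dir, paste0(stem, "_regions.csv"))
  utils::write.csv(section$truth$regions, csv, row.names = FALSE)
  js <- file.path(dir, paste0(stem, "_params.json"))
  sp <- section$spec
  sp$orr_field <- if (is.function(sp$orr_field)) "function" else
    sp$orr_field
  jsonlite::write_json(unclass(sp), js, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(tiff = tif, regions = csv, params = js))
}
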
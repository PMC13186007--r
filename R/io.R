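# Table readers/writers, pipeline configuration and the end-to-end
# driver: simulate -> segment -> classify -> fit-density -> quantify ->
# cortical -> stats -> report.

.region_cols <- c("eye_id", "condition", "region_id", "x_start_um",
                  "mean_orr")
.spike_cols <- c("stim_electrode", "channel", "hemisphere", "x_mm",
                 "y_mm", "current_uA", "spikes")

.check_columns <- function(df, mandatory, what) {
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop(what, " lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  invisible(df)
}

#' Read / write the region table
#'
#' CSV with one row per 250 micron region. Mandatory columns: `eye_id`,
#' `condition`, `region_id`, `x_start_um`, `mean_orr`; unknown columns
#' are preserved on a round trip.
#'
#' @param path CSV path.
#' @param regions Region data frame.
#' @return `read_region_table` returns the data frame;
#'   `write_region_table` returns `path` invisibly.
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stop("region table not found: ", path)
  .check_columns(utils::read.csv(path), .region_cols, "region table")
}

#' @rdname read_region_table
#' @export
write_region_table <- function(regions, path) {
  .check_columns(regions, .region_cols, "region table")
  utils::write.csv(regions, path, row.names = FALSE)
  invisible(path)
}

#' Read a spike-count table
#'
#' Long-format CSV: `stim_electrode`, `channel`, `hemisphere`, `x_mm`,
#' `y_mm`, `current_uA`, `spikes`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_spike_table <- function(path) {
  if (!file.exists(path)) stop("spike table not found: ", path)
  .check_columns(utils::read.csv(path), .spike_cols, "spike table")
}

#' Write a generic metric table
#'
#' @param table Data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write a density fit as JSON
#'
#' @param fit An [fit_onl_density()] object.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_density_fit <- function(fit, path) {
  stopifnot(inherits(fit, "onl_density_fit"))
  jsonlite::write_json(
    list(A = fit$A, B = fit$B, r2_db = fit$r2_db, rmse_db = fit$rmse_db,
         F = fit$F, S = fit$S, n = fit$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated bag of parameters for [run_pipeline()]. Any field can also be
#' supplied through a YAML file via `config_file`.
#'
#' @param seed RNG seed for the whole run.
#' @param out_dir Output directory.
#' @param control_length_um,treated_length_um Synthetic section extents.
#' @param px_per_um Pixel calibration.
#' @param region_length_um,interval_um Region geometry.
#' @param cutoffs Group cutoffs, strictly decreasing
#'   (`mild_moderate`, `moderate_severe`).
#' @param sd_multiplier Normative SDs below the mean.
#' @param dab_method,dab_od_threshold DAB classification rule.
#' @param n_electrodes_per_group Cortical battery size per group.
#' @param cortical_noise `"poisson"` or `"none"`.
#' @param config_file Optional YAML file whose keys override the
#'   defaults (arguments override the file).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("orr_run_"),
                            control_length_um = 2000,
                            treated_length_um = 3000,
                            px_per_um = 2,
                            region_length_um = 250, interval_um = 50,
                            cutoffs = c(mild_moderate = 0.35,
                                        moderate_severe = 0.2),
                            sd_multiplier = 2,
                            dab_method = "deconvolution",
                            dab_od_threshold = 0.15,
                            n_electrodes_per_group = 10,
                            cortical_noise = "poisson",
                            config_file = NULL) {
  cfg <- as.list(environment())
  cfg$config_file <- NULL
  if (!is.null(config_file)) {
    yml <- yaml::read_yaml(config_file)
    supplied <- names(match.call())[-1]
    for (k in setdiff(intersect(names(yml), names(cfg)), supplied))
      cfg[[k]] <- if (k == "cutoffs") unlist(yml[[k]]) else yml[[k]]
  }
  with(cfg, {
    if (region_length_um <= 0 || interval_um <= 0 || px_per_um <= 0 ||
        control_length_um <= 0 || treated_length_um <= 0)
      stop("all lengths and calibrations must be positive")
    if (cutoffs[["mild_moderate"]] <= cutoffs[["moderate_severe"]])
      stop("group cutoffs must be strictly decreasing")
  })
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates one control and one treated eye, recovers layer profiles
#' from the rendered label masks, measures and grades all regions,
#' fits the normative and density models, quantifies markers on the
#' rendered channels, simulates and analyses a cortical battery, runs the
#' group statistics, and writes every artifact (CSV/JSON plus a markdown
#' report) to `config$out_dir`. Every artifact is reproducible from
#' (config, seed).
#'
#' @param config A [pipeline_config()].
#' @return Object of class `orr_pipeline`: list with `regions`,
#'   `normative`, `density_fit`, `markers`, `cortical`, `stats`,
#'   `distribution`, `exclusions`, `paths`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log_msg <- function(...) message("[orrquant] ", sprintf(...))

  # --- simulate ---------------------------------------------------------
  eyes <- list(
    control = generate_section(section_spec(
      length_um = config$control_length_um, px_per_um = config$px_per_um,
      condition = "control", region_length_um = config$region_length_um,
      interval_um = config$interval_um,
      seed = config$seed)),
    treated = generate_section(section_spec(
      length_um = config$treated_length_um, px_per_um = config$px_per_um,
      condition = "treated", region_length_um = config$region_length_um,
      interval_um = config$interval_um,
      seed = config$seed + 1L)))

  # --- geometry: profiles from the rendered label masks -----------------
  regions <- do.call(rbind, lapply(names(eyes), function(nm) {
    prof <- profile_from_mask(eyes[[nm]]$label_mask, config$px_per_um)
    measure_regions(prof, eye_id = nm, condition = nm,
                    region_length_um = config$region_length_um,
                    interval_um = config$interval_um)
  }))

  # --- normative model and grading --------------------------------------
  normative <- fit_normative(
    regions$mean_orr[regions$condition == "control" & regions$measurable],
    sd_multiplier = config$sd_multiplier)
  regions <- classify_regions(regions, normative, config$cutoffs)
  distribution <- group_distribution(regions$group, regions$eye_id)
  n_unmeas <- sum(!regions$measurable)
  if (n_unmeas) log_msg("%d unmeasurable region(s) excluded", n_unmeas)

  # --- density model: count ONL nuclei on the DAPI channel --------------
  onl <- do.call(rbind, lapply(names(eyes), function(nm) {
    sec <- eyes[[nm]]
    sub <- regions[regions$eye_id == nm, ]
    px <- config$px_per_um
    do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
      if (!photoreceptor_quantifiable(sub$group[i], sub$measurable[i]))
        return(NULL)
      cols <- which((seq_len(ncol(sec$label_mask)) - 0.5) / px >=
                      sub$x_start_um[i] &
                      (seq_len(ncol(sec$label_mask)) - 0.5) / px <
                      sub$x_start_um[i] + config$region_length_um)
      band <- sec$label_mask == 5L   # ONL
      band[, setdiff(seq_len(ncol(band)), cols)] <- FALSE
      if (!any(band)) return(NULL)
      ns <- count_nuclei(sec$images$dapi, band, px)
      data.frame(eye_id = nm, region_id = sub$region_id[i],
                 mean_orr = sub$mean_orr[i], group = sub$group[i],
                 onl_count = ns$count, onl_per_mm = ns$count_per_mm)
    }))
  }))
  skipped_pr <- sum(!photoreceptor_quantifiable(regions$group,
                                                regions$measurable))
  if (skipped_pr) log_msg(
    "%d region(s) skipped for photoreceptor markers (group 4/indeterminate)",
    skipped_pr)
  density_fit <- fit_onl_density(onl$mean_orr, onl$onl_per_mm)

  # --- markers -----------------------------------------------------------
  markers <- do.call(rbind, lapply(names(eyes), function(nm) {
    sec <- eyes[[nm]]
    sub <- regions[regions$eye_id == nm, ]
    px <- config$px_per_um
    do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
      cols_log <- (seq_len(ncol(sec$label_mask)) - 0.5) / px >=
        sub$x_start_um[i] &
        (seq_len(ncol(sec$label_mask)) - 0.5) / px <
        sub$x_start_um[i] + config$region_length_um
      region_mask <- matrix(rep(cols_log, each = nrow(sec$label_mask)),
                            nrow(sec$label_mask))
      out <- list()
      if (photoreceptor_quantifiable(sub$group[i], sub$measurable[i])) {
        os_mask <- sec$label_mask == 7L & region_mask
        ch_mask <- sec$truth$choroid_mask & region_mask
        if (any(os_mask) && any(ch_mask)) {
          fi <- fluorescence_intensity(sec$images$marker, os_mask, ch_mask)
          out$rho <- data.frame(eye_id = nm, region_id = sub$region_id[i],
                                group = sub$group[i], marker = "rhodopsin",
                                layer = "OS", kind = "intensity",
                                value = as.numeric(fi))
        }
      }
      ipl_mask <- sec$label_mask == 2L & region_mask
      if (any(ipl_mask)) {
        da <- dab_positive_area(sec$images$dab, ipl_mask, px,
                                method = config$dab_method,
                                od_threshold = config$dab_od_threshold)
        out$dab <- data.frame(eye_id = nm, region_id = sub$region_id[i],
                              group = sub$group[i], marker = "calbindin",
                              layer = "IPL", kind = "area_per_length",
                              value = as.numeric(da))
      }
      nuc <- sec$truth$nuclei
      gsel <- nuc$layer == "GCL" & nuc$x_um >= sub$x_start_um[i] &
        nuc$x_um < sub$x_start_um[i] + config$region_length_um
      if (sum(gsel) > 0) {
        out$rbpms <- data.frame(eye_id = nm, region_id = sub$region_id[i],
                                group = sub$group[i], marker = "RBPMS",
                                layer = "GCL", kind = "ratio",
                                value = rbpms_ratio(sum(nuc$rbpms[gsel]),
                                                    sum(gsel)))
      }
      do.call(rbind, out)
    }))
  }))
  # normalize rhodopsin to same-animal control mean
  ctrl_mean <- mean(markers$value[markers$marker == "rhodopsin" &
                                    markers$eye_id == "control"])
  rho_rows <- markers$marker == "rhodopsin"
  markers$value[rho_rows] <- normalize_to_control(markers$value[rho_rows],
                                                  ctrl_mean)
  markers$kind[rho_rows] <- "normalized_intensity"

  # --- cortical ----------------------------------------------------------
  battery <- generate_cortical_battery(
    n_per_group = config$n_electrodes_per_group,
    seed = config$seed + 2L, noise = config$cortical_noise)
  cortical <- do.call(rbind, lapply(battery$responses, function(r) {
    bt <- best_threshold(r$table)
    dp <- tryCatch(dprime_selectivity(r$table)$d_prime,
                   error = function(e) NA_real_)
    data.frame(stim_electrode = r$table$stim_electrode[1],
               group = r$truth$group,
               best_threshold_uA = as.numeric(bt), d_prime = dp,
               true_threshold_uA = r$truth$threshold_uA,
               true_d_prime = r$truth$d_prime)
  }))
  # synthetic region-above-electrode link: ORr drawn within the group's
  # range so retina-to-cortex correlations can be exercised
  rng <- rbind(`0` = c(0.44, 0.64), `1` = c(0.44, 0.64),
               `2` = c(0.35, 0.44), `3` = c(0.2, 0.35),
               `4` = c(0.0, 0.2))
  cortical$region_orr <- stats::runif(nrow(cortical),
                                      rng[as.character(cortical$group), 1],
                                      rng[as.character(cortical$group), 2])

  # --- statistics --------------------------------------------------------
  thr_groups <- split(cortical$best_threshold_uA, cortical$group)
  thr_groups <- lapply(thr_groups, function(v) v[is.finite(v)])
  stats_out <- list(
    threshold_by_group = kw_dunn(thr_groups),
    correlations = correlation_matrix(
      cortical, retinal_metrics = "region_orr",
      cortical_metrics = c("best_threshold_uA", "d_prime")))

  # --- write artifacts ---------------------------------------------------
  paths <- c(
    regions = write_region_table(regions,
                                 file.path(config$out_dir, "regions.csv")),
    onl = write_metric_table(onl, file.path(config$out_dir,
                                            "onl_counts.csv")),
    density = write_density_fit(density_fit,
                                file.path(config$out_dir,
                                          "density_fit.json")),
    markers = write_metric_table(markers,
                                 file.path(config$out_dir, "markers.csv")),
    cortical = write_metric_table(cortical,
                                  file.path(config$out_dir,
                                            "cortical.csv")),
    pairwise = write_metric_table(stats_out$threshold_by_group$pairwise,
                                  file.path(config$out_dir,
                                            "threshold_dunn.csv")),
    correlations = write_metric_table(
      as.data.frame(stats_out$correlations),
      file.path(config$out_dir, "correlations.csv")))
  report <- file.path(config$out_dir, "report.md")
  .write_report(report, normative, distribution, density_fit, cortical,
                stats_out)
  paths <- c(paths, report = report)

  structure(list(regions = regions, normative = normative,
                 density_fit = density_fit, markers = markers,
                 cortical = cortical, stats = stats_out,
                 distribution = distribution,
                 exclusions = c(unmeasurable = n_unmeas,
                                photoreceptor_skipped = skipped_pr),
                 paths = paths, config = config),
            class = "orr_pipeline")
}

.write_report <- function(path, normative, distribution, density_fit,
                          cortical, stats_out) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# ORr pipeline report\n")
  w("## Normative model\n")
  w("Control mean ORr %.3f (SD %.3f, n = %d); threshold (mean - %g SD) = %.3f (%.1fth percentile under a normal model).\n",
    normative$mu, normative$sigma, normative$n, normative$sd_multiplier,
    normative$threshold, normative_percentile(normative))
  w("## Group distribution (pooled)\n")
  w("| group | n |\n|---|---|")
  for (g in names(distribution$pooled))
    w("| %s | %d |", g, distribution$pooled[[g]])
  w("\n## ONL density model\n")
  w("10*log10(CD) = %.2f + %.2f * ORr; R2_dB %.3f, RMSE_dB %.2f dB, F %.2fx, Duan S %.3f (n = %d).\n",
    density_fit$A, density_fit$B, density_fit$r2_db, density_fit$rmse_db,
    density_fit$F, density_fit$S, density_fit$n)
  w("## Cortical thresholds by group\n")
  agg <- stats::aggregate(best_threshold_uA ~ group, cortical, mean)
  w("| group | mean best threshold (uA) |\n|---|---|")
  for (i in seq_len(nrow(agg))) w("| %d | %.1f |", agg$group[i],
                                  agg$best_threshold_uA[i])
  w("\nKruskal-Wallis H = %.2f (df %d, p = %.3g).",
    stats_out$threshold_by_group$H, stats_out$threshold_by_group$df,
    stats_out$threshold_by_group$p_global)
  invisible(path)
}

#' @export
print.orr_pipeline <- function(x, ...) {
  cat("ORr pipeline run\n")
  print(x$normative)
  cat("Pooled group counts:\n"); print(x$distribution$pooled)
  print(x$density_fit)
  cat(sprintf("Cortical: %d electrodes; outputs in %s\n",
              nrow(x$cortical), x$config$out_dir))
  invisible(x)
}
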
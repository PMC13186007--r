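# Normative ORr threshold and degeneration-group assignment.
#
# Treated regions are graded against a normative threshold derived from
# control eyes (mean ORr minus 2 SD); fixed cutoffs at 0.35 and 0.2 further
# split degenerated regions into mild/moderate/severe.

#' Group labels
#'
#' Group 0 holds all control-eye regions regardless of ORr; treated regions
#' are split into 1 (no degeneration, ORr at or above the normative
#' threshold), 2 (mild, below threshold but >= 0.35), 3 (moderate,
#' < 0.35 but >= 0.2) and 4 (severe, < 0.2).
#'
#' @param group Integer vector of group values in 0..4 (NA allowed).
#' @return Character vector of group names.
#' @export
group_name <- function(group) {
  nm <- c("control", "none", "mild", "moderate", "severe")
  out <- rep(NA_character_, length(group))
  ok <- !is.na(group) & group %in% 0:4
  out[ok] <- nm[group[ok] + 1L]
  out
}

#' Fit the normative ORr model from control regions
#'
#' The normative threshold separating "no degeneration" from degenerated
#' regions is the control mean ORr minus `sd_multiplier` (default 2)
#' standard deviations. The SD uses the sample (n - 1) denominator. The
#' threshold is carried at full precision; printed summaries round to 2
#' decimals.
#'
#' @param control_orr Numeric vector of per-region mean ORr values from
#'   control eyes, each in [0, 1], length >= 2.
#' @param sd_multiplier Number of SDs below the mean (default 2).
#' @return Object of class `orr_normative`: list with `mu`, `sigma`,
#'   `threshold`, `sd_multiplier`, `n`.
#' @examples
#' m <- fit_normative(c(0.5, 0.5, 0.6, 0.6))
#' m$threshold   # 0.55 - 2 * 0.0577 = 0.4345
#' @export
fit_normative <- function(control_orr, sd_multiplier = 2) {
  control_orr <- control_orr[!is.na(control_orr)]
  if (length(control_orr) < 2L)
    stop("need at least 2 control ORr values")
  if (any(control_orr < 0 | control_orr > 1))
    stop("ORr values must lie in [0, 1]")
  mu <- mean(control_orr)
  sigma <- stats::sd(control_orr)
  structure(list(mu = mu, sigma = sigma,
                 threshold = mu - sd_multiplier * sigma,
                 sd_multiplier = sd_multiplier,
                 n = length(control_orr)),
            class = "orr_normative")
}

#' @export
print.orr_normative <- function(x, ...) {
  cat(sprintf(
    "Normative ORr model (n = %d control regions)\n  mean %.3f, SD %.3f\n  threshold (mean - %g SD): %.2f\n",
    x$n, x$mu, x$sigma, x$sd_multiplier, x$threshold))
  invisible(x)
}

#' @export
coef.orr_normative <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma, threshold = object$threshold)
}

#' Percentile of the normative threshold under a normal model
#'
#' Under a normal model for control ORr, the mean minus 2 SD threshold sits
#' at the 100 * pnorm(-2) = 2.275th percentile (2.3 to one decimal) of the
#' control distribution.
#'
#' @param model An [fit_normative()] fit with `sigma > 0`.
#' @return Percentile (0-100) of the threshold.
#' @export
normative_percentile <- function(model) {
  stopifnot(inherits(model, "orr_normative"))
  if (model$sigma <= 0)
    stop("percentile undefined: control SD is zero")
  100 * stats::pnorm((model$threshold - model$mu) / model$sigma)
}

#' Assign degeneration groups
#'
#' Control regions are group 0 regardless of ORr. Treated regions with mean
#' ORr at or above the normative threshold are group 1; otherwise cutoffs
#' at 0.35 and 0.2 (closed lower bounds: exactly 0.35 is group 2, exactly
#' 0.2 is group 3) split mild/moderate/severe. Unmeasurable regions get NA
#' ("indeterminate") and are excluded from group statistics.
#'
#' @param mean_orr Numeric vector of region mean ORr.
#' @param condition Character vector (recycled), `"control"` or `"treated"`.
#' @param model An [fit_normative()] fit.
#' @param cutoffs Named numeric `c(mild_moderate = 0.35,
#'   moderate_severe = 0.2)`; must be strictly decreasing and below the
#'   normative threshold.
#' @param measurable Logical vector (recycled); FALSE yields NA.
#' @return Integer vector of groups in 0..4 (NA = indeterminate).
#' @export
classify_region <- function(mean_orr, condition, model,
                            cutoffs = c(mild_moderate = 0.35,
                                        moderate_severe = 0.2),
                            measurable = TRUE) {
  stopifnot(inherits(model, "orr_normative"))
  if (cutoffs[["mild_moderate"]] <= cutoffs[["moderate_severe"]])
    stop("cutoffs must be strictly decreasing")
  if (cutoffs[["mild_moderate"]] >= model$threshold)
    warning("mild/moderate cutoff at or above the normative threshold; ",
            "group 2 is empty")
  n <- length(mean_orr)
  condition <- rep_len(condition, n)
  measurable <- rep_len(measurable, n)
  if (!all(condition %in% c("control", "treated")))
    stop("condition must be 'control' or 'treated'")
  g <- rep(NA_integer_, n)
  ok <- measurable & !is.na(mean_orr)
  g[ok & condition == "control"] <- 0L
  tr <- ok & condition == "treated"
  g[tr & mean_orr >= model$threshold] <- 1L
  g[tr & mean_orr < model$threshold &
      mean_orr >= cutoffs[["mild_moderate"]]] <- 2L
  g[tr & mean_orr < cutoffs[["mild_moderate"]] &
      mean_orr >= cutoffs[["moderate_severe"]]] <- 3L
  g[tr & mean_orr < cutoffs[["moderate_severe"]]] <- 4L
  g
}

#' Augment a region table with group labels
#'
#' @param regions Region table as from [measure_regions()].
#' @inheritParams classify_region
#' @return The table with `group` and `group_name` columns appended.
#' @export
classify_regions <- function(regions, model,
                             cutoffs = c(mild_moderate = 0.35,
                                         moderate_severe = 0.2)) {
  need <- c("mean_orr", "condition", "measurable")
  miss <- setdiff(need, names(regions))
  if (length(miss))
    stop("region table lacks columns: ", paste(miss, collapse = ", "))
  regions$group <- classify_region(regions$mean_orr, regions$condition,
                                   model, cutoffs, regions$measurable)
  regions$group_name <- group_name(regions$group)
  regions
}

#' Per-eye and pooled group distribution
#'
#' @param group Integer group vector (NA = indeterminate, counted in
#'   `n_indeterminate` but excluded from proportions).
#' @param eye_id Eye identifier vector (recycled).
#' @return List with `per_eye` (counts matrix, eyes x groups), `pooled`
#'   (named counts), `proportions` (per-eye rows summing to 1), and
#'   `n_indeterminate`.
#' @export
group_distribution <- function(group, eye_id = "eye1") {
  if (!length(group)) stop("no labelled regions")
  eye_id <- rep_len(eye_id, length(group))
  keep <- !is.na(group)
  f <- factor(group[keep], levels = 0:4)
  per_eye <- table(eye = eye_id[keep], group = f)
  pooled <- colSums(per_eye)
  props <- sweep(per_eye, 1L, pmax(rowSums(per_eye), 1L), "/")
  list(per_eye = unclass(per_eye), pooled = pooled,
       proportions = unclass(props),
       n_indeterminate = sum(!keep))
}
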
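# Log-linear ONL cell-density model:  10*log10(CD_ONL) = A + B * ORr
#
# The fit lives in decibel space (10*log10 of cells/mm); goodness of fit is
# reported there (R2_dB, RMSE_dB) together with its fold-scale equivalents:
# the multiplicative RMSE factor F = 10^(RMSE_dB/10) and the Duan smearing
# factor S = mean over residuals r of 10^(r/10), which retransforms
# log-space predictions toward the conditional arithmetic mean.

#' Decibel transform of cell densities
#'
#' @param density Cell densities (cells/mm), strictly positive.
#' @return `10 * log10(density)` (dB).
#' @export
db <- function(density) 10 * log10(density)

#' Multiplicative RMSE factor
#'
#' The fold-error equivalent of a dB-scale RMSE: `10^(rmse_db / 10)`. A
#' dB RMSE of 1.96 corresponds to a factor of about 1.57.
#'
#' @param rmse_db Root-mean-square residual in dB.
#' @return Fold factor (>= 1 for rmse_db >= 0).
#' @export
rmse_factor <- function(rmse_db) 10^(rmse_db / 10)

#' Duan smearing factor
#'
#' Mean of the back-transformed regression residuals,
#' `mean(10^(residuals_db / 10))`. For a least-squares fit with intercept
#' the residuals average zero, so by Jensen's inequality S >= 1; for
#' Gaussian residuals with SD sigma dB it converges to
#' `exp((sigma * log(10) / 10)^2 / 2)`.
#'
#' @param residuals_db Regression residuals in dB.
#' @return Smearing factor S (fold).
#' @export
smearing_factor <- function(residuals_db) mean(10^(residuals_db / 10))

#' Fit the log-linear ONL density model
#'
#' Ordinary least squares of `10*log10(density)` on ORr. Regions whose ONL
#' could not be counted must be excluded upstream (severe degeneration
#' obscures ONL delineation).
#'
#' @param orr Region mean ORr values.
#' @param density ONL cell densities (cells per mm of retina), all > 0.
#' @param rmse_denominator `"n"` (default) or `"df"` (n - 2) for the RMSE.
#' @return Object of class `onl_density_fit` with elements `A` (intercept,
#'   dB), `B` (slope, dB per ORr unit), `r2_db`, `rmse_db`, `F`
#'   (multiplicative RMSE factor), `S` (Duan smearing factor), `n`,
#'   `residuals_db`, `fitted_db`, and the data.
#' @examples
#' d <- simulate_onl_density(200, seed = 1)
#' fit <- fit_onl_density(d$orr, d$density)
#' coef(fit)
#' predict(fit, orr = 0.44)              # median-scale prediction
#' predict(fit, orr = 0.44, smeared = TRUE)  # mean-scale (Duan) prediction
#' @export
fit_onl_density <- function(orr, density, rmse_denominator = c("n", "df")) {
  rmse_denominator <- match.arg(rmse_denominator)
  stopifnot(length(orr) == length(density))
  keep <- !(is.na(orr) | is.na(density))
  orr <- orr[keep]; density <- density[keep]
  bad <- which(density <= 0)
  if (length(bad))
    stop("non-positive density at index ", paste(utils::head(bad, 5L),
                                                 collapse = ", "))
  if (length(orr) < 3L) stop("need at least 3 observations")
  if (stats::var(orr) == 0) stop("zero ORr variance: slope unidentifiable")
  y <- db(density)
  fit <- stats::lm(y ~ orr)
  r <- stats::residuals(fit)
  n <- length(y)
  denom <- if (rmse_denominator == "n") n else n - 2L
  rmse <- sqrt(sum(r^2) / denom)
  sst <- sum((y - mean(y))^2)
  structure(list(
    A = unname(stats::coef(fit)[1L]),
    B = unname(stats::coef(fit)[2L]),
    r2_db = 1 - sum(r^2) / sst,
    rmse_db = rmse,
    F = rmse_factor(rmse),
    S = smearing_factor(r),
    n = n,
    residuals_db = unname(r),
    fitted_db = unname(stats::fitted(fit)),
    se = suppressWarnings(sqrt(diag(stats::vcov(fit)))),
    orr = orr, density = density,
    rmse_denominator = rmse_denominator),
    class = "onl_density_fit")
}

#' @export
coef.onl_density_fit <- function(object, ...) {
  c(A = object$A, B = object$B)
}

#' @export
residuals.onl_density_fit <- function(object, ...) object$residuals_db

#' Predict ONL density from ORr
#'
#' The median-style back-transform is `10^((A + B * orr) / 10)`; with
#' `smeared = TRUE` it is multiplied by the Duan smearing factor S, giving
#' a prediction of the conditional arithmetic mean rather than the median.
#'
#' @param object An [fit_onl_density()] fit.
#' @param orr ORr values in [0, 1].
#' @param smeared Apply the smearing retransformation? Default FALSE.
#' @param ... Unused.
#' @return Predicted cells/mm.
#' @export
predict.onl_density_fit <- function(object, orr, smeared = FALSE, ...) {
  if (any(orr < 0 | orr > 1, na.rm = TRUE))
    stop("ORr must lie in [0, 1]")
  out <- 10^((object$A + object$B * orr) / 10)
  if (smeared) out <- out * object$S
  out
}

#' @export
print.onl_density_fit <- function(x, ...) {
  cat(sprintf(
    "Log-linear ONL density fit (n = %d)\n  10*log10(CD) = %.2f + %.2f * ORr\n",
    x$n, x$A, x$B))
  cat(sprintf(
    "  R2_dB = %.3f, RMSE_dB = %.2f dB (F = %.2fx), smearing S = %.3f\n",
    x$r2_db, x$rmse_db, x$F, x$S))
  invisible(x)
}

#' @export
summary.onl_density_fit <- function(object, ...) {
  out <- list(
    coefficients = cbind(Estimate = c(A = object$A, B = object$B),
                         `Std. Error` = object$se),
    r2_db = object$r2_db, rmse_db = object$rmse_db,
    F = object$F, S = object$S, n = object$n)
  class(out) <- "summary.onl_density_fit"
  out
}

#' @export
print.summary.onl_density_fit <- function(x, ...) {
  cat("Log-linear ONL density model (dB scale)\n\nCoefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf(
    "\nn = %d, R2_dB = %.3f, RMSE_dB = %.3f dB\nF = %.3fx (fold RMSE), Duan S = %.4f\n",
    x$n, x$r2_db, x$rmse_db, x$F, x$S))
  invisible(x)
}

#' @export
plot.onl_density_fit <- function(x, smeared = FALSE, ...) {
  graphics::plot(x$orr, x$density, log = "y",
                 xlab = "ORr", ylab = "ONL cells / mm",
                 pch = 16, col = grDevices::grey(0.4, 0.6), ...)
  xs <- seq(min(x$orr), max(x$orr), length.out = 100)
  graphics::lines(xs, predict(x, xs), lty = 2)
  if (smeared) graphics::lines(xs, predict(x, xs, smeared = TRUE), lty = 3)
  invisible(x)
}
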
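# Droplet quantification: threshold, count, Poisson-correct.
# This is the computation the droplet reader's software performs: the
# positive-droplet fraction p is converted to mean copies per droplet
# lambda = -ln(1 - p), which accounts for droplets holding more than one
# template, and then to copies per microliter via the droplet volume.

#' Set the positive/negative amplitude threshold
#'
#' The default \code{control_anchored} method pools the amplitudes of the
#' plate's control wells (NTC-LB and/or no-primer) and places the threshold
#' \code{k} standard deviations above their mean; with \code{k = 7} the
#' per-droplet false-positive rate under a Gaussian negative band is far
#' below 1/17,000. \code{k_sigma} derives the same statistic from the target
#' well's own lower (negative) mode by iteratively trimming droplets more
#' than 3 SD above the running mean. \code{fixed} passes a user value
#' through.
#'
#' @param controls List of [droplet_well()] control wells (may be empty for
#'   methods other than \code{control_anchored}).
#' @param method \code{"control_anchored"} (default), \code{"k_sigma"} or
#'   \code{"fixed"}.
#' @param k Multiplier on the negative-band SD (default 7).
#' @param value Threshold value for \code{method = "fixed"}.
#' @param target Target [droplet_well()] for \code{method = "k_sigma"}.
#' @return An object of class \code{threshold_decision} with the threshold,
#'   the method and its parameters, and the control summary used.
#' @export
set_threshold <- function(controls = list(),
                          method = c("control_anchored", "k_sigma", "fixed"),
                          k = 7, value = NULL, target = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value) || !is.finite(value))
      stop("`value` must be supplied for the fixed method", call. = FALSE)
    return(structure(list(threshold = value, method = method, k = NA_real_,
                          control_summary = NULL),
                     class = "threshold_decision"))
  }
  if (method == "control_anchored") {
    if (length(controls) == 0L)
      stop("control_anchored thresholding needs at least one control well",
           call. = FALSE)
    a <- unlist(lapply(controls, function(w) w$amplitudes), use.names = FALSE)
  } else { # k_sigma: lower mode of the target well
    if (is.null(target))
      stop("`target` well must be supplied for the k_sigma method",
           call. = FALSE)
    a <- target$amplitudes
    repeat {
      cut <- mean(a) + 3 * stats::sd(a)
      a2 <- a[a <= cut]
      if (length(a2) == length(a)) break
      a <- a2
    }
  }
  m <- mean(a)
  s <- stats::sd(a)
  structure(
    list(threshold = m + k * s, method = method, k = k,
         control_summary = list(mean = m, sd = s, n_droplets = length(a))),
    class = "threshold_decision"
  )
}

#' @export
print.threshold_decision <- function(x, ...) {
  cat(sprintf("Threshold %.1f a.u. (method %s", x$threshold, x$method))
  if (!is.na(x$k)) cat(sprintf(", k = %g", x$k))
  cat(")\n")
  if (!is.null(x$control_summary))
    cat(sprintf("  negative band: mean %.1f, SD %.1f over %d droplets\n",
                x$control_summary$mean, x$control_summary$sd,
                x$control_summary$n_droplets))
  invisible(x)
}

#' Count positive and total droplets in a well
#'
#' A droplet is positive when its amplitude is strictly above the threshold;
#' droplets exactly at the threshold count as negative (amplitude exports are
#' discrete-valued, so the tie rule is explicit).
#'
#' @param well A [droplet_well()].
#' @param threshold A [set_threshold()] decision or a bare numeric threshold.
#' @return An object of class \code{droplet_counts} with \code{n_total} and
#'   \code{n_positive}.
#' @export
count_droplets <- function(well, threshold) {
  stopifnot(inherits(well, "droplet_well"))
  thr <- if (inherits(threshold, "threshold_decision")) threshold$threshold
    else as.numeric(threshold)
  if (length(well$amplitudes) == 0L)
    stop("well has no droplets", call. = FALSE)
  structure(
    list(n_total = length(well$amplitudes),
         n_positive = sum(well$amplitudes > thr)),
    class = "droplet_counts"
  )
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

# Clopper-Pearson exact interval.
clopper_pearson_interval <- function(x, n, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  low <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(low = low, high = high)
}

#' Poisson-corrected concentration estimate from droplet counts
#'
#' Converts the positive fraction \eqn{\hat p = n_{pos}/n_{tot}} into the
#' mean copies per droplet \eqn{\hat\lambda = -\ln(1 - \hat p)} — the
#' standard digital-PCR estimator, which corrects for droplets containing
#' multiple template molecules — and then into molecules per microliter via
#' the droplet volume. The 95\% confidence interval is a Wilson score
#' interval on \eqn{\hat p}, each bound transformed through the same
#' \eqn{-\ln(1-\cdot)} map (Clopper-Pearson available via
#' \code{ci_method = "clopper-pearson"}).
#'
#' @param counts A [count_droplets()] result (or list with \code{n_total},
#'   \code{n_positive}).
#' @param droplet_volume_nl Droplet volume in nanoliters (default 0.85).
#' @param conf_level Confidence level (default 0.95).
#' @param ci_method \code{"wilson"} (default) or \code{"clopper-pearson"}.
#' @return An object of class \code{concentration_estimate} with
#'   \code{lambda_hat}, \code{copies_per_ul}, \code{ci_low_per_ul},
#'   \code{ci_high_per_ul}, the counts and the droplet volume.
#' @export
estimate_concentration <- function(counts, droplet_volume_nl = 0.85,
                                   conf_level = 0.95,
                                   ci_method = c("wilson", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  n <- counts$n_total
  x <- counts$n_positive
  if (is.null(n) || is.null(x) || n <= 0 || x < 0 || x > n)
    stop("invalid droplet counts", call. = FALSE)
  if (droplet_volume_nl <= 0)
    stop("`droplet_volume_nl` must be positive", call. = FALSE)
  if (x == n)
    stop("all droplets positive: the Poisson estimate is undefined at ",
         "saturation; dilute the sample and re-run", call. = FALSE)
  p <- x / n
  lambda <- -log1p(-p)
  vol_ul <- droplet_volume_nl * 1e-3
  ci_p <- if (ci_method == "wilson") wilson_interval(x, n, conf_level)
    else clopper_pearson_interval(x, n, conf_level)
  ci_p <- pmin(ci_p, 1 - 1 / (2 * n))  # keep the transform finite
  structure(
    list(lambda_hat = lambda,
         copies_per_ul = lambda / vol_ul,
         ci_low_per_ul = -log1p(-ci_p[["low"]]) / vol_ul,
         ci_high_per_ul = -log1p(-ci_p[["high"]]) / vol_ul,
         counts = list(n_total = n, n_positive = x),
         droplet_volume_nl = droplet_volume_nl,
         conf_level = conf_level, ci_method = ci_method),
    class = "concentration_estimate"
  )
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("%.2f copies/ul (95%% CI %.2f-%.2f), lambda = %.5f, %d/%d droplets positive\n",
              x$copies_per_ul, x$ci_low_per_ul, x$ci_high_per_ul,
              x$lambda_hat, x$counts$n_positive, x$counts$n_total))
  invisible(x)
}

#' Total telomerase products in the PCR
#'
#' Scales a concentration estimate to total extension products by the PCR
#' volume (copies/ul x 20 for the standard 20 ul reaction); confidence
#' bounds scale identically.
#'
#' @param est A [estimate_concentration()] result or a bare copies/ul value.
#' @param pcr_volume_ul PCR volume in microliters (default 20).
#' @return For an estimate object, a list with \code{total},
#'   \code{ci_low} and \code{ci_high} (molecules); for a bare value, the
#'   scaled number.
#' @export
total_products <- function(est, pcr_volume_ul = 20) {
  if (pcr_volume_ul <= 0)
    stop("`pcr_volume_ul` must be positive", call. = FALSE)
  if (inherits(est, "concentration_estimate")) {
    list(total = est$copies_per_ul * pcr_volume_ul,
         ci_low = est$ci_low_per_ul * pcr_volume_ul,
         ci_high = est$ci_high_per_ul * pcr_volume_ul)
  } else {
    as.numeric(est) * pcr_volume_ul
  }
}
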
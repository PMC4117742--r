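# Downstream assay analyses: replicate CV tables, limiting-dilution
# linearity, single-cell population summaries, 4PL dose-response IC50 and
# stimulation time-course comparison.

#' Coefficient of variation, in percent
#'
#' \code{SD / mean x 100}, rounded to 2 decimals; the assay's
#' reproducibility metric for replicate activity measurements. Undefined
#' (\code{NA}) when the mean is not positive.
#'
#' @param sd Standard deviation of the replicate measurements.
#' @param mean Mean of the replicate measurements.
#' @return CV in percent, rounded to 2 decimals.
#' @export
cv_percent <- function(sd, mean) {
  ifelse(is.finite(mean) & mean > 0, round(sd / mean * 100, 2), NA_real_)
}

#' Replicate CV table by cell-equivalent group
#'
#' Groups sample rows of an activity table by their cell-equivalent input and
#' reports per group the replicate count, mean and sample SD (n - 1
#' denominator) of total products, and the CV\%. Groups of size 1 are kept
#' but flagged with an undefined CV.
#'
#' @param results An [process_plate()] activity table, or any data frame with
#'   \code{total_products} and a grouping column.
#' @param group_col Grouping column (default \code{"cell_equivalents"}).
#' @return Data frame with \code{group_label}, \code{n_replicates},
#'   \code{mean_total_products}, \code{sd_total_products} and
#'   \code{cv_percent}.
#' @export
cv_table <- function(results, group_col = "cell_equivalents") {
  df <- as.data.frame(results)
  if ("role" %in% names(df)) df <- df[df$role == "sample", , drop = FALSE]
  if ("qc_pass" %in% names(df)) df <- df[df$qc_pass, , drop = FALSE]
  if (nrow(df) == 0L) stop("no sample rows to summarize", call. = FALSE)
  groups <- split(df$total_products, df[[group_col]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    m <- mean(v)
    s <- if (length(v) >= 2L) stats::sd(v) else NA_real_
    data.frame(group_label = g, n_replicates = length(v),
               mean_total_products = m, sd_total_products = s,
               cv_percent = if (length(v) >= 2L) cv_percent(s, m) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  ord <- suppressWarnings(as.numeric(out$group_label))
  if (!anyNA(ord)) out <- out[order(-ord), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares fit of a limiting-dilution series
#'
#' Fits total telomerase products against cell-equivalent input by OLS and
#' reports the slope (molecules per cell equivalent), intercept and
#' \eqn{R^2} (squared Pearson correlation of fitted vs observed, identical
#' to the OLS coefficient of determination). An \eqn{R^2} of 0.98-0.99
#' over a 100-to-6.25 cell-equivalent series is the assay's linearity
#' benchmark.
#'
#' @param cell_eq Numeric vector of cell-equivalent inputs.
#' @param total_products Numeric vector of total products, same length.
#' @return An object of class \code{dilution_fit} with \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{n_points} and the underlying
#'   \code{lm} fit.
#' @export
fit_dilution_series <- function(cell_eq, total_products) {
  stopifnot(length(cell_eq) == length(total_products))
  if (length(unique(cell_eq)) < 3L)
    stop("a dilution fit needs at least 3 distinct cell-equivalent levels",
         call. = FALSE)
  fit <- stats::lm(total_products ~ cell_eq)
  # squared Pearson correlation of fitted vs observed (the OLS R^2)
  r2 <- stats::cor(stats::fitted(fit), total_products)^2
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_points = length(cell_eq),
         fit = fit),
    class = "dilution_fit"
  )
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat(sprintf("Dilution linearity: slope %.2f molecules/cell eq, intercept %.1f, R^2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.dilution_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Summarize a single-cell cohort
#'
#' Counts positive wells via each record's positive call and summarizes
#' per-cell activity. \code{mean_activity_positive} averages total products
#' over positive cells only (each well holds one cell, so total products are
#' per-cell products); \code{sem} is the standard error over positive cells.
#' The positive percentage is reported to the nearest whole percent.
#'
#' @param results Activity table rows from single-cell wells
#'   (\code{cell_equivalents == 1}).
#' @return An object of class \code{single_cell_summary} with
#'   \code{n_cells}, \code{n_positive}, \code{positive_fraction},
#'   \code{positive_percent}, \code{mean_activity_all},
#'   \code{mean_activity_positive} and \code{sem}.
#' @export
summarize_single_cells <- function(results) {
  df <- as.data.frame(results)
  if ("role" %in% names(df)) df <- df[df$role == "sample", , drop = FALSE]
  if (nrow(df) == 0L) stop("no single-cell records supplied", call. = FALSE)
  if ("cell_equivalents" %in% names(df) &&
      any(df$cell_equivalents != 1))
    stop("all records must have cell_equivalents = 1", call. = FALSE)
  pos <- as.logical(df$positive_call)
  n <- nrow(df)
  np <- sum(pos)
  act_pos <- df$total_products[pos]
  structure(
    list(n_cells = n,
         n_positive = np,
         positive_fraction = np / n,
         positive_percent = round(np / n * 100),
         mean_activity_all = mean(df$total_products),
         mean_activity_positive = if (np > 0) mean(act_pos) else NA_real_,
         sem = if (np >= 2) stats::sd(act_pos) / sqrt(np) else NA_real_),
    class = "single_cell_summary"
  )
}

#' @export
print.single_cell_summary <- function(x, ...) {
  cat(sprintf("Single cells: %d of %d positive (%d%%)\n",
              x$n_positive, x$n_cells, x$positive_percent))
  if (!is.na(x$mean_activity_positive))
    cat(sprintf("  mean activity of positive cells: %.1f +/- %.1f molecules (mean +/- SEM)\n",
                x$mean_activity_positive, x$sem))
  invisible(x)
}

#' Relative telomerase activity vs an untreated control group
#'
#' Divides each treated measurement by the mean of the control group, the
#' normalization used for inhibitor dose-response data.
#'
#' @param treated Numeric vector of treated total products (or an activity
#'   table subset, in which case \code{total_products} is used).
#' @param control Numeric vector (or table subset) of control measurements.
#' @return Numeric vector of ratios, one per treated measurement.
#' @export
relative_activity <- function(treated, control) {
  get_vals <- function(x) if (is.data.frame(x)) x$total_products else
    as.numeric(x)
  tr <- get_vals(treated)
  ct <- get_vals(control)
  m <- mean(ct)
  if (!is.finite(m) || m <= 0)
    stop("control group mean must be positive", call. = FALSE)
  tr / m
}

# 4PL inhibition curve: rel = bottom + (top - bottom) / (1 + (d / ic50)^hill).
# At zero dose the curve equals top exactly, so untreated replicates anchor
# the upper plateau.
four_pl <- function(dose, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Four-parameter logistic dose-response fit (IC50)
#'
#' Least-squares fit of relative activity against dose with the
#' four-parameter logistic
#' \deqn{y = bottom + (top - bottom) / (1 + (d/IC_{50})^{h})}
#' (top free near 1, bottom free near 0, Hill slope free; the zero-dose
#' group anchors the top plateau since the curve equals \code{top} at
#' \eqn{d = 0}). The IC50 is the dose halfway between the fitted plateaus.
#' When the optimizer fails or the data show no real inhibition, the fit is
#' flagged non-convergent and a log-linear interpolation between the dose
#' groups bracketing 50\% of the plateau span is reported as a fallback.
#'
#' @param dose_uM Dose vector (uM), including zero-dose controls.
#' @param relative_activity Relative activity (treated / untreated mean),
#'   same length.
#' @return An object of class \code{ic50_fit} with \code{top},
#'   \code{bottom}, \code{hill_slope}, \code{ic50}, \code{converged},
#'   \code{method} (\code{"4pl"} or \code{"interpolation"}) and a residual
#'   summary (\code{rss}, \code{sigma}).
#' @export
fit_ic50 <- function(dose_uM, relative_activity) {
  stopifnot(length(dose_uM) == length(relative_activity))
  if (length(unique(dose_uM)) < 4L || !any(dose_uM == 0))
    stop("the dose-response fit needs >= 4 dose levels including 0",
         call. = FALSE)
  d <- dose_uM
  y <- relative_activity
  gm <- tapply(y, d, mean)
  gd <- as.numeric(names(gm))
  top0 <- unname(gm[gd == 0])
  bottom0 <- min(gm)
  span <- top0 - bottom0

  fit <- NULL
  if (span > 0.2 * top0) {
    half_level <- bottom0 + span / 2
    pos <- gd > 0
    below <- which(pos & gm <= half_level)
    ic50_0 <- if (length(below)) min(gd[below]) else max(gd[pos])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + (d / exp(lic50))^hill),
        start = list(top = top0, bottom = max(0, bottom0),
                     lic50 = log(ic50_0), hill = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    res <- stats::resid(fit)
    ic50 <- exp(unname(cf["lic50"]))
    ok <- is.finite(ic50) && ic50 > 0 && unname(cf["hill"]) > 0 &&
      unname(cf["top"]) > unname(cf["bottom"])
    if (ok) {
      return(structure(
        list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
             hill_slope = unname(cf["hill"]), ic50 = ic50,
             converged = TRUE, method = "4pl",
             rss = sum(res^2), sigma = stats::sigma(fit), fit = fit),
        class = "ic50_fit"))
    }
  }

  # Fallback: log-linear interpolation of dose-group means to the level
  # halfway between the empirical plateaus.
  half_level <- bottom0 + span / 2
  ic50 <- NA_real_
  pos <- gd > 0
  if (span > 0) {
    gmp <- gm[pos]; gdp <- gd[pos]
    idx <- which(gmp <= half_level)
    if (length(idx) && min(idx) > 1L) {
      i <- min(idx)
      x1 <- log(gdp[i - 1]); x2 <- log(gdp[i])
      y1 <- gmp[i - 1]; y2 <- gmp[i]
      ic50 <- exp(x1 + (half_level - y1) * (x2 - x1) / (y2 - y1))
    }
  }
  structure(
    list(top = top0, bottom = bottom0, hill_slope = NA_real_, ic50 = ic50,
         converged = FALSE, method = "interpolation",
         rss = NA_real_, sigma = NA_real_, fit = NULL),
    class = "ic50_fit"
  )
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("4PL dose-response: IC50 = %.3g uM (top %.3f, bottom %.3f, Hill %.2f)\n",
                x$ic50, x$top, x$bottom, x$hill_slope))
  } else {
    cat(sprintf("Dose-response fit did not converge; interpolation fallback IC50 = %s uM\n",
                ifelse(is.na(x$ic50), "NA (no inhibition detected)",
                       sprintf("%.3g", x$ic50))))
  }
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom,
    hill_slope = object$hill_slope, ic50 = object$ic50)
}

#' Simulate relative-activity dose-response data
#'
#' Draws replicate relative-activity values from a four-parameter logistic
#' inhibition curve with multiplicative Gaussian noise at a given CV — the
#' dose design used in the inhibitor experiment (six doses including zero,
#' nine extracts per dose, ~9\% CV).
#'
#' @param dose_uM Dose levels (uM).
#' @param ic50 True IC50 (uM).
#' @param hill Hill slope (default 1).
#' @param top,bottom Plateaus (defaults 1 and 0).
#' @param n_replicates Replicates per dose (default 9).
#' @param cv Multiplicative noise CV (default 0.09).
#' @param seed Integer seed; \code{NULL} uses the current RNG state.
#' @return Data frame with \code{dose_uM}, \code{replicate} and
#'   \code{relative_activity}.
#' @export
simulate_relative_activity <- function(dose_uM, ic50, hill = 1, top = 1,
                                       bottom = 0, n_replicates = 9,
                                       cv = 0.09, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- rep(dose_uM, each = n_replicates)
  mu <- four_pl(d, top, bottom, ic50, hill)
  y <- mu * (1 + stats::rnorm(length(d), 0, cv))
  data.frame(dose_uM = d,
             replicate = rep(seq_len(n_replicates), times = length(dose_uM)),
             relative_activity = pmax(0, y))
}

#' Compare activity time points against a baseline by paired t-tests
#'
#' For mitogen-stimulation time courses: replicates are paired across
#' timepoints by their replicate index, and each non-baseline timepoint is
#' tested against baseline with a two-sided paired Student's t-test. No
#' multiplicity adjustment is applied by default; \code{adjust = "bonferroni"}
#' enables it.
#'
#' @param results Activity table (or data frame) with \code{timepoint},
#'   \code{replicate} and \code{total_products} columns.
#' @param baseline Label of the baseline timepoint.
#' @param value_col Measurement column (default \code{"total_products"}).
#' @param adjust \code{"none"} (default) or \code{"bonferroni"}.
#' @return Data frame with one row per timepoint: \code{timepoint}, \code{n},
#'   \code{mean}, \code{sem}, and for non-baseline rows \code{t_statistic},
#'   \code{df}, \code{p_value} (and \code{p_adjusted} when requested).
#' @export
compare_timepoints <- function(results, baseline,
                               value_col = "total_products",
                               adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  df <- as.data.frame(results)
  if ("role" %in% names(df)) df <- df[df$role == "sample", , drop = FALSE]
  need <- c("timepoint", "replicate", value_col)
  if (!all(need %in% names(df)))
    stop("results must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!baseline %in% df$timepoint)
    stop("baseline timepoint not found in the data", call. = FALSE)
  tps <- unique(df$timepoint)
  base <- df[df$timepoint == baseline, , drop = FALSE]
  base <- base[order(base$replicate), , drop = FALSE]
  if (nrow(base) < 2L)
    stop("paired testing needs at least 2 replicate pairs", call. = FALSE)

  rows <- lapply(tps, function(tp) {
    g <- df[df$timepoint == tp, , drop = FALSE]
    g <- g[order(g$replicate), , drop = FALSE]
    v <- g[[value_col]]
    row <- data.frame(timepoint = tp, n = nrow(g), mean = mean(v),
                      sem = stats::sd(v) / sqrt(nrow(g)),
                      t_statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_, stringsAsFactors = FALSE)
    if (tp != baseline) {
      if (nrow(g) != nrow(base) || !all(g$replicate == base$replicate))
        stop("replicate indices at timepoint '", tp,
             "' do not pair with the baseline", call. = FALSE)
      diffs <- v - base[[value_col]]
      if (stats::sd(diffs) == 0) {
        # degenerate pairs: identical shifts give no sampling variance
        row$t_statistic <- if (mean(diffs) == 0) 0 else
          sign(mean(diffs)) * Inf
        row$df <- length(diffs) - 1
        row$p_value <- if (mean(diffs) == 0) 1 else 0
      } else {
        tt <- stats::t.test(v, base[[value_col]], paired = TRUE)
        row$t_statistic <- unname(tt$statistic)
        row$df <- unname(tt$parameter)
        row$p_value <- tt$p.value
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  if (adjust == "bonferroni")
    out$p_adjusted <- pmin(1, out$p_value * sum(!is.na(out$p_value)))
  rownames(out) <- NULL
  out
}
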
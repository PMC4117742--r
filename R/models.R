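#' Generative model of a cell population's telomerase activity
#'
#' A `cell_model` describes how many telomerase extension products individual
#' cells of a population generate during the standard 40-minute extension
#' reaction. The population is a two-component mixture: a fraction of cells is
#' telomerase-inactive (zero products), and active cells draw their product
#' count from a gamma-mixed Poisson (negative binomial) with a given mean and
#' gamma-shape dispersion.
#'
#' @param label Preset name or free-text label.
#' @param fraction_active Proportion of cells with any telomerase activity,
#'   in \code{[0, 1]}.
#' @param mean_products_per_active_cell Expected extension products generated
#'   by one active cell during a standard 40-minute extension (molecules).
#' @param dispersion Gamma-shape parameter of the active-cell product-count
#'   distribution; larger values mean less overdispersion, \code{Inf} gives
#'   the pure Poisson limit.
#'
#' @return An object of class \code{cell_model}.
#' @seealso [cell_preset()] for named presets, [draw_cell_products()].
#' @export
cell_model <- function(label, fraction_active, mean_products_per_active_cell,
                       dispersion = 8) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(fraction_active) || fraction_active < 0 || fraction_active > 1)
    stop("`fraction_active` must be in [0, 1]", call. = FALSE)
  if (!is.numeric(mean_products_per_active_cell) ||
      mean_products_per_active_cell < 0)
    stop("`mean_products_per_active_cell` must be >= 0", call. = FALSE)
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop("`dispersion` must be > 0", call. = FALSE)
  structure(
    list(label = label,
         fraction_active = fraction_active,
         mean_products_per_active_cell = mean_products_per_active_cell,
         dispersion = dispersion),
    class = "cell_model"
  )
}

#' @export
print.cell_model <- function(x, ...) {
  cat("Cell model:", x$label, "\n")
  cat(sprintf("  fraction active: %.2f\n", x$fraction_active))
  cat(sprintf("  mean products per active cell: %.1f molecules (40-min extension)\n",
              x$mean_products_per_active_cell))
  cat(sprintf("  dispersion (gamma shape): %s\n", format(x$dispersion)))
  invisible(x)
}

#' Named cell-population presets
#'
#' Presets encode the cell populations used throughout the assay's validation
#' experiments:
#' \describe{
#'   \item{\code{hela_single_cell}}{HeLa in the one-step lysis-extension,
#'     single-cell regime: 73\% of cells active, active cells averaging 57.8
#'     extension products per 40-minute extension.}
#'   \item{\code{hela_bulk}}{HeLa bulk lysate in the two-step protocol,
#'     scaled so a population cell-equivalent yields 15.87 products
#'     (0.73 x 21.74), matching the replicate-dilution activity scale of
#'     100-cell-equivalent reactions (~1590 total products).}
#'   \item{\code{telomerase_negative}}{ALT-like negative control line,
#'     no active cells.}
#' }
#'
#' @param name One of \code{"hela_single_cell"}, \code{"hela_bulk"},
#'   \code{"telomerase_negative"}.
#' @return A [cell_model()].
#' @export
cell_preset <- function(name = c("hela_single_cell", "hela_bulk",
                                 "telomerase_negative")) {
  name <- match.arg(name)
  switch(name,
    hela_single_cell = cell_model("hela_single_cell",
                                  fraction_active = 0.73,
                                  mean_products_per_active_cell = 57.8,
                                  dispersion = 8),
    hela_bulk = cell_model("hela_bulk",
                           fraction_active = 0.73,
                           mean_products_per_active_cell = 21.74,
                           dispersion = 8),
    telomerase_negative = cell_model("telomerase_negative",
                                     fraction_active = 0,
                                     mean_products_per_active_cell = 0,
                                     dispersion = 8)
  )
}

#' Protocol constants for the lysis-extension-PCR dilution chain
#'
#' Captures the bookkeeping volumes of one sample's path from cell lysis to
#' droplet PCR, plus the droplet-generation geometry. Defaults mirror the
#' standard two-step assay: 50,000 cells lysed in 40 ul (1250 cells/ul), 1 ul
#' of lysate into a 50 ul extension (25 cells/ul), 2 ul of extension into a
#' 20 ul PCR (50 cell equivalents), ~20,000 droplets of 0.85 nl generated and
#' ~17,000 read.
#'
#' @param cells_lysed Number of cells lysed.
#' @param lysis_volume_ul Lysis volume (ul).
#' @param lysate_into_extension_ul Lysate volume carried into extension (ul).
#' @param extension_volume_ul Extension reaction volume (ul).
#' @param extension_minutes Extension duration (minutes); 40 is the standard.
#' @param extension_into_pcr_ul Extension volume carried into the PCR (ul).
#' @param pcr_volume_ul PCR volume (ul).
#' @param droplet_volume_nl Droplet volume (nl).
#' @param droplets_generated Droplets produced by the generator.
#' @param droplets_read Droplets actually read by the instrument.
#' @param single_step \code{TRUE} for the combined lysis-extension (single-cell)
#'   variant, where the cell count passes through the chain unchanged.
#'
#' @return An object of class \code{protocol_spec}.
#' @export
protocol_spec <- function(cells_lysed = 50000,
                          lysis_volume_ul = 40,
                          lysate_into_extension_ul = 1,
                          extension_volume_ul = 50,
                          extension_minutes = 40,
                          extension_into_pcr_ul = 2,
                          pcr_volume_ul = 20,
                          droplet_volume_nl = 0.85,
                          droplets_generated = 20000,
                          droplets_read = 17000,
                          single_step = FALSE) {
  vols <- c(lysis_volume_ul, lysate_into_extension_ul, extension_volume_ul,
            extension_into_pcr_ul, pcr_volume_ul, droplet_volume_nl)
  if (any(!is.finite(vols)) || any(vols <= 0))
    stop("all protocol volumes must be positive", call. = FALSE)
  if (cells_lysed < 0) stop("`cells_lysed` must be >= 0", call. = FALSE)
  if (extension_minutes <= 0)
    stop("`extension_minutes` must be > 0", call. = FALSE)
  if (droplets_read > droplets_generated)
    stop("`droplets_read` cannot exceed `droplets_generated`", call. = FALSE)
  if (lysate_into_extension_ul > extension_volume_ul)
    stop("lysate volume cannot exceed the extension volume", call. = FALSE)
  if (extension_into_pcr_ul > pcr_volume_ul)
    stop("extension aliquot cannot exceed the PCR volume", call. = FALSE)
  structure(
    list(cells_lysed = cells_lysed,
         lysis_volume_ul = lysis_volume_ul,
         lysate_into_extension_ul = lysate_into_extension_ul,
         extension_volume_ul = extension_volume_ul,
         extension_minutes = extension_minutes,
         extension_into_pcr_ul = extension_into_pcr_ul,
         pcr_volume_ul = pcr_volume_ul,
         droplet_volume_nl = droplet_volume_nl,
         droplets_generated = droplets_generated,
         droplets_read = droplets_read,
         single_step = isTRUE(single_step)),
    class = "protocol_spec"
  )
}

#' Single-cell (one-step lysis-extension) protocol preset
#'
#' One cell dissolved in a 2 ul combined lysis-extension reaction, to which
#' 18 ul of droplet-PCR mix is added, so the entire extension enters the
#' 20 ul PCR and the cell equivalent is exactly the cell count.
#'
#' @param cells Cells captured per well (1 for true single-cell wells).
#' @param ... Overrides passed to [protocol_spec()].
#' @return A \code{protocol_spec} with \code{single_step = TRUE}.
#' @export
single_cell_protocol <- function(cells = 1, ...) {
  protocol_spec(cells_lysed = cells,
                lysis_volume_ul = 2,
                lysate_into_extension_ul = 2,
                extension_volume_ul = 2,
                extension_into_pcr_ul = 2,
                pcr_volume_ul = 20,
                single_step = TRUE,
                ...)
}

#' Saturating extension kinetics
#'
#' Extension yield follows a single-exponential saturation
#' \eqn{y(t) = 1 - e^{-kt}}. The default rate is solved so that the standard
#' 40-minute extension recovers 75\% of the 2-hour yield,
#' i.e. \eqn{y(40)/y(120) = 0.75}.
#'
#' @param rate_k Per-minute saturation rate; \code{NULL} (default) solves the
#'   rate from \code{yield_ratio} at 40 vs 120 minutes.
#' @param yield_ratio Target \eqn{y(40)/y(120)} used when \code{rate_k} is
#'   \code{NULL}.
#' @return An object of class \code{extension_kinetics}.
#' @export
extension_kinetics <- function(rate_k = NULL, yield_ratio = 0.75) {
  if (is.null(rate_k)) {
    if (yield_ratio <= 1 / 3 || yield_ratio >= 1)
      stop("`yield_ratio` for 40 vs 120 min must lie in (1/3, 1)", call. = FALSE)
    rate_k <- stats::uniroot(
      function(k) (1 - exp(-40 * k)) / (1 - exp(-120 * k)) - yield_ratio,
      interval = c(1e-8, 5), tol = 1e-12
    )$root
  }
  if (!is.numeric(rate_k) || rate_k <= 0)
    stop("`rate_k` must be > 0", call. = FALSE)
  structure(list(rate_k = rate_k), class = "extension_kinetics")
}

#' Extension yield at a given duration
#'
#' @param kinetics An [extension_kinetics()].
#' @param minutes Extension duration(s) in minutes.
#' @return Yield fraction(s) in (0, 1), monotone increasing in \code{minutes}.
#' @export
extension_yield <- function(kinetics, minutes) {
  stopifnot(inherits(kinetics, "extension_kinetics"))
  1 - exp(-kinetics$rate_k * minutes)
}

#' Two-band droplet fluorescence amplitude model
#'
#' Endpoint fluorescence of a droplet is drawn from a negative band (no
#' template) or a positive band (at least one template), both Gaussian in
#' arbitrary instrument units. An optional "rain" band of intermediate
#' amplitude captures template-containing droplets that amplify poorly.
#' Only the separability of the bands matters; the default positions are
#' arbitrary instrument-scale values.
#'
#' @param mu_negative,sd_negative Negative-band mean and SD (a.u.).
#' @param mu_positive,sd_positive Positive-band mean and SD (a.u.).
#' @param rain_fraction Proportion in \code{[0, 1)} of template-containing
#'   droplets drawn from the intermediate band instead of the positive band.
#' @return An object of class \code{amplitude_model}.
#' @export
amplitude_model <- function(mu_negative = 1000, sd_negative = 50,
                            mu_positive = 5000, sd_positive = 200,
                            rain_fraction = 0) {
  if (mu_positive <= mu_negative)
    stop("`mu_positive` must exceed `mu_negative`", call. = FALSE)
  if (sd_negative <= 0 || sd_positive <= 0)
    stop("band SDs must be positive", call. = FALSE)
  if (rain_fraction < 0 || rain_fraction >= 1)
    stop("`rain_fraction` must be in [0, 1)", call. = FALSE)
  structure(
    list(mu_negative = mu_negative, sd_negative = sd_negative,
         mu_positive = mu_positive, sd_positive = sd_positive,
         rain_fraction = rain_fraction),
    class = "amplitude_model"
  )
}
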
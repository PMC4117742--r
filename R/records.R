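#' Sample record: the dilution-chain bookkeeping for one well
#'
#' Holds the cell counts and volumes that define how many cell equivalents of
#' lysate material reached the PCR, plus free-form condition labels used by
#' the downstream analyses (dose, timepoint).
#'
#' @param sample_id Sample identifier.
#' @param well_id Well identifier (unique within a plate).
#' @param role One of \code{"sample"}, \code{"ntc_lb"}, \code{"no_primer"}.
#' @param protocol A [protocol_spec()] supplying the volumes; alternatively
#'   pass the individual volume fields.
#' @param cells_lysed,lysis_volume_ul,lysate_into_extension_ul Chain fields
#'   (override the protocol's values when given).
#' @param extension_volume_ul,extension_into_pcr_ul,pcr_volume_ul More chain
#'   fields.
#' @param single_step \code{TRUE} for one-step lysis-extension records, whose
#'   cell count passes through the chain unchanged.
#' @param dose,timepoint Optional condition labels.
#' @param replicate Optional replicate index (used for pairing in
#'   time-course analyses).
#' @return An object of class \code{sample_record}.
#' @export
sample_record <- function(sample_id, well_id, role = "sample",
                          protocol = NULL,
                          cells_lysed = NULL, lysis_volume_ul = NULL,
                          lysate_into_extension_ul = NULL,
                          extension_volume_ul = NULL,
                          extension_into_pcr_ul = NULL,
                          pcr_volume_ul = NULL, single_step = NULL,
                          dose = NULL, timepoint = NULL, replicate = NULL) {
  pick <- function(x, field, default) {
    if (!is.null(x)) x
    else if (!is.null(protocol)) protocol[[field]]
    else default
  }
  rec <- list(
    sample_id = as.character(sample_id),
    well_id = as.character(well_id),
    role = match.arg(role, c("sample", "ntc_lb", "no_primer")),
    cells_lysed = pick(cells_lysed, "cells_lysed", 0),
    lysis_volume_ul = pick(lysis_volume_ul, "lysis_volume_ul", 40),
    lysate_into_extension_ul = pick(lysate_into_extension_ul,
                                    "lysate_into_extension_ul", 1),
    extension_volume_ul = pick(extension_volume_ul, "extension_volume_ul", 50),
    extension_into_pcr_ul = pick(extension_into_pcr_ul,
                                 "extension_into_pcr_ul", 2),
    pcr_volume_ul = pick(pcr_volume_ul, "pcr_volume_ul", 20),
    single_step = isTRUE(pick(single_step, "single_step", FALSE)),
    dose = if (is.null(dose)) NA_real_ else as.numeric(dose),
    timepoint = if (is.null(timepoint)) NA_character_ else as.character(timepoint),
    replicate = if (is.null(replicate)) NA_integer_ else as.integer(replicate)
  )
  vols <- c(rec$lysis_volume_ul, rec$lysate_into_extension_ul,
            rec$extension_volume_ul, rec$extension_into_pcr_ul,
            rec$pcr_volume_ul)
  if (any(!is.finite(vols)) || any(vols <= 0))
    stop("all sample-record volumes must be positive", call. = FALSE)
  if (rec$cells_lysed < 0)
    stop("`cells_lysed` must be >= 0", call. = FALSE)
  structure(rec, class = "sample_record")
}

#' Dilution-chain concentrations for a sample record
#'
#' Returns the intermediate concentrations of the lysis-extension-PCR chain:
#' lysate cells/ul (cells lysed / lysis volume), extension cells/ul, and the
#' resulting cell equivalents in the PCR. For the canonical chain (50,000
#' cells in 40 ul; 1 ul into a 50 ul extension; 2 ul into the PCR) these are
#' 1250 cells/ul, 25 cells/ul and 50 cell equivalents.
#'
#' @param rec A [sample_record()].
#' @return List with \code{lysate_cells_per_ul}, \code{extension_cells_per_ul}
#'   and \code{cell_equivalents}.
#' @export
dilution_chain <- function(rec) {
  stopifnot(inherits(rec, "sample_record"))
  lys <- rec$cells_lysed / rec$lysis_volume_ul
  ext <- lys * rec$lysate_into_extension_ul / rec$extension_volume_ul
  list(lysate_cells_per_ul = lys,
       extension_cells_per_ul = ext,
       cell_equivalents = ext * rec$extension_into_pcr_ul)
}

#' Cell equivalents present in the PCR
#'
#' The deterministic dilution-chain product
#' \code{cells_lysed / lysis_volume x lysate_into_extension /
#' extension_volume x extension_into_pcr}. Single-step (one-step
#' lysis-extension) records pass their cell count through unchanged, since
#' the whole reaction enters the PCR.
#'
#' @param rec A [sample_record()].
#' @return Cell equivalents (cells) in the PCR.
#' @export
cell_equivalents <- function(rec) {
  stopifnot(inherits(rec, "sample_record"))
  if (rec$single_step) return(rec$cells_lysed)
  dilution_chain(rec)$cell_equivalents
}
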
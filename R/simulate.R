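# Synthetic assay generator: stands in for the wet lab and the droplet
# reader so every downstream stage is testable without instrument data.

#' Construct a droplet well
#'
#' The instrument-facing record: one fluorescence amplitude per read droplet
#' plus well metadata. Simulated wells additionally carry the true molecule
#' count that entered the PCR (ground truth unavailable for real exports).
#'
#' @param well_id Unique well identifier.
#' @param role One of \code{"sample"}, \code{"ntc_lb"} (no-template
#'   lysis-buffer control) or \code{"no_primer"}.
#' @param amplitudes Numeric vector of droplet fluorescence amplitudes (a.u.).
#' @param true_molecule_count Optional ground-truth molecules in the PCR.
#' @param occupied Optional logical vector: true template occupancy of each
#'   read droplet (simulated wells only).
#' @return An object of class \code{droplet_well}.
#' @export
droplet_well <- function(well_id, role = c("sample", "ntc_lb", "no_primer"),
                         amplitudes, true_molecule_count = NA_real_,
                         occupied = NULL) {
  role <- match.arg(role)
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) < 1L || any(!is.finite(amplitudes)))
    stop("`amplitudes` must be a non-empty vector of finite values",
         call. = FALSE)
  structure(
    list(well_id = as.character(well_id), role = role,
         amplitudes = amplitudes,
         true_molecule_count = true_molecule_count,
         occupied = occupied),
    class = "droplet_well"
  )
}

#' @export
print.droplet_well <- function(x, ...) {
  cat(sprintf("Droplet well %s (%s): %d droplets, amplitude range [%.0f, %.0f]\n",
              x$well_id, x$role, length(x$amplitudes),
              min(x$amplitudes), max(x$amplitudes)))
  if (!is.na(x$true_molecule_count))
    cat(sprintf("  simulated; true molecules in PCR: %d\n",
                as.integer(x$true_molecule_count)))
  invisible(x)
}

# Deterministic per-well child seed from the plate's master seed.
# Counter scheme: child_i = (48271 * master + 2654435769 * i) mod (2^31 - 1),
# kept in exact double arithmetic (< 2^53) so results are platform-stable.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  as.integer((48271 * (as.double(seed) %% 44488) +
                (2654435769 * as.double(index)) %% 2147483647) %% 2147483647)
}

#' Draw per-cell telomerase extension-product counts
#'
#' Each cell is inactive (zero products) with probability
#' \code{1 - fraction_active}; active cells draw from a negative binomial
#' (gamma-mixed Poisson) with the model's mean and gamma-shape dispersion.
#' \code{dispersion = Inf} gives the pure Poisson limit.
#'
#' @param model A [cell_model()].
#' @param n_cells Number of cells to draw.
#' @param seed Integer seed; \code{NULL} uses the current RNG state.
#' @return Integer vector of length \code{n_cells} of product counts.
#' @export
draw_cell_products <- function(model, n_cells, seed = NULL) {
  stopifnot(inherits(model, "cell_model"))
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 0)
    stop("`n_cells` must be a non-negative count", call. = FALSE)
  n_cells <- as.integer(n_cells)
  if (!is.null(seed)) set.seed(seed)
  if (n_cells == 0L) return(integer(0))
  active <- stats::runif(n_cells) < model$fraction_active
  out <- integer(n_cells)
  n_act <- sum(active)
  if (n_act > 0L && model$mean_products_per_active_cell > 0) {
    out[active] <- if (is.infinite(model$dispersion)) {
      stats::rpois(n_act, model$mean_products_per_active_cell)
    } else {
      stats::rnbinom(n_act, size = model$dispersion,
                     mu = model$mean_products_per_active_cell)
    }
  }
  out
}

# Stochastic (binomial) or expectation-level thinning of discrete molecules.
thin_count <- function(n, fraction, thinning = c("binomial", "expected")) {
  thinning <- match.arg(thinning)
  stopifnot(fraction >= 0, fraction <= 1)
  n <- as.integer(round(n))
  if (n == 0L || fraction == 1) return(n)
  if (thinning == "binomial") stats::rbinom(1L, n, fraction)
  else as.integer(round(n * fraction))
}

#' Simulate the telomerase extension reaction
#'
#' A binomial thinning of the lysed cells (at rate
#' \code{lysate_into_extension_ul / lysis_volume_ul}) selects which cells'
#' products enter the extension; the summed molecule count is then scaled by
#' the kinetic factor \code{yield(t) / yield(40)}, which is exactly 1 at the
#' standard 40-minute duration. Single-step protocols carry all cells in.
#'
#' @param products_per_cell Integer vector of per-cell product counts for the
#'   lysed cells (at the standard 40-minute yield).
#' @param protocol A [protocol_spec()].
#' @param kinetics An [extension_kinetics()].
#' @param seed Integer seed; \code{NULL} uses the current RNG state.
#' @param thinning \code{"binomial"} (molecule-level sampling) or
#'   \code{"expected"} (deterministic fractions, for expectation-level tests).
#' @return List with \code{molecules} (count in the extension),
#'   \code{concentration_per_ul} (molecules/ul of extension),
#'   \code{cells_in_extension} and the kinetic \code{scale} applied.
#' @export
simulate_extension <- function(products_per_cell, protocol,
                               kinetics = extension_kinetics(), seed = NULL,
                               thinning = c("binomial", "expected")) {
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(kinetics, "extension_kinetics"))
  thinning <- match.arg(thinning)
  if (!is.null(seed)) set.seed(seed)
  n <- length(products_per_cell)
  frac <- protocol$lysate_into_extension_ul / protocol$lysis_volume_ul
  if (protocol$single_step || frac >= 1) {
    sel <- rep(TRUE, n)
  } else if (thinning == "binomial") {
    sel <- stats::runif(n) < frac
  } else {
    k <- as.integer(round(n * frac))
    sel <- c(rep(TRUE, k), rep(FALSE, n - k))
  }
  base <- sum(products_per_cell[sel])
  scale <- extension_yield(kinetics, protocol$extension_minutes) /
    extension_yield(kinetics, 40)
  molecules <- if (scale == 1) {
    base
  } else if (scale < 1) {
    thin_count(base, scale, thinning)
  } else if (thinning == "binomial") {
    base + stats::rpois(1L, base * (scale - 1))
  } else {
    as.integer(round(base * scale))
  }
  list(molecules = as.integer(molecules),
       concentration_per_ul = molecules / protocol$extension_volume_ul,
       cells_in_extension = sum(sel),
       scale = scale)
}

#' Partition molecules into droplets
#'
#' Multinomial assignment of each template molecule to one of
#' \code{droplets_generated} equal-probability droplets; the per-droplet
#' counts always sum to the input exactly. The molecules supplied here are
#' those present in the emulsified volume (see [simulate_plate()] for the
#' aliquoting and emulsion-capture thinning that precede partitioning).
#'
#' @param molecules Non-negative template count.
#' @param protocol A [protocol_spec()] (uses \code{droplets_generated}).
#' @param seed Integer seed; \code{NULL} uses the current RNG state.
#' @return Integer vector of per-droplet counts, length
#'   \code{droplets_generated}.
#' @export
partition_into_droplets <- function(molecules, protocol, seed = NULL) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (!is.numeric(molecules) || molecules < 0)
    stop("`molecules` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- protocol$droplets_generated
  molecules <- as.integer(round(molecules))
  if (molecules == 0L) return(integer(d))
  counts <- tabulate(sample.int(d, molecules, replace = TRUE), nbins = d)
  as.integer(counts)
}

#' Render per-droplet template counts into a read droplet well
#'
#' Occupied droplets (>= 1 template) draw their endpoint amplitude from the
#' positive band, or from an intermediate "rain" band with probability
#' \code{rain_fraction}; empty droplets draw from the negative band. A
#' uniform random subset of \code{droplets_read} droplets is retained,
#' emulating the reader's incomplete droplet recovery.
#'
#' @param per_droplet_counts Integer vector of length
#'   \code{droplets_generated}.
#' @param amp An [amplitude_model()].
#' @param protocol A [protocol_spec()].
#' @param well_id,role Metadata for the resulting well.
#' @param true_molecule_count Ground-truth molecules in the PCR to carry.
#' @param seed Integer seed; \code{NULL} uses the current RNG state.
#' @return A [droplet_well()] with \code{droplets_read} amplitudes and the
#'   true occupancy of the retained droplets.
#' @export
render_amplitudes <- function(per_droplet_counts, amp, protocol,
                              well_id = "A01", role = "sample",
                              true_molecule_count = NA_real_, seed = NULL) {
  stopifnot(inherits(amp, "amplitude_model"),
            inherits(protocol, "protocol_spec"))
  d <- protocol$droplets_generated
  if (length(per_droplet_counts) != d)
    stop("`per_droplet_counts` must have length `droplets_generated`",
         call. = FALSE)
  if (protocol$droplets_read > d)
    stop("`droplets_read` cannot exceed `droplets_generated`", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  occ <- per_droplet_counts > 0L
  a <- stats::rnorm(d, amp$mu_negative, amp$sd_negative)
  n_occ <- sum(occ)
  if (n_occ > 0L) {
    rain <- stats::runif(n_occ) < amp$rain_fraction
    pos_amp <- stats::rnorm(n_occ, amp$mu_positive, amp$sd_positive)
    if (any(rain)) {
      mu_rain <- (amp$mu_negative + amp$mu_positive) / 2
      sd_rain <- (amp$sd_negative + amp$sd_positive) / 2
      pos_amp[rain] <- stats::rnorm(sum(rain), mu_rain, sd_rain)
    }
    a[occ] <- pos_amp
  }
  keep <- if (protocol$droplets_read < d)
    sort(sample.int(d, protocol$droplets_read)) else seq_len(d)
  droplet_well(well_id = well_id, role = role, amplitudes = a[keep],
               true_molecule_count = true_molecule_count,
               occupied = occ[keep])
}

#' Simulate a full assay plate
#'
#' Generates every well of a plate: for each sample well, per-cell products
#' are drawn from its cell model, carried through lysis/extension thinning and
#' kinetics, aliquoted into the PCR (binomial thinning at
#' \code{extension_into_pcr_ul / extension_volume_ul}), and joined by an
#' independent Poisson(\code{background_mean_per_ul} x \code{pcr_volume_ul})
#' contaminating count. Of the PCR's molecules, the fraction occupying the
#' emulsified volume (\code{droplets_generated} x \code{droplet_volume_nl} /
#' \code{pcr_volume_ul}, capped at 1) is captured into droplets, partitioned
#' multinomially and rendered to amplitudes. NTC-LB wells receive background
#' only; no-primer wells render entirely from the negative band.
#'
#' Reproducibility: one master seed per plate; each well uses a child seed
#' derived from the master seed and the well counter, so identical seeds
#' reproduce identical plates bit-for-bit.
#'
#' @param samples List of sample descriptors, each a list with elements
#'   \code{model} (a [cell_model()]), \code{protocol} (a [protocol_spec()]),
#'   \code{n_replicates}, and optionally \code{sample_id}, \code{dose},
#'   \code{timepoint}.
#' @param background_mean_per_ul Mean background contamination
#'   (molecules per ul of PCR); default 1.5.
#' @param amp An [amplitude_model()].
#' @param kinetics An [extension_kinetics()].
#' @param seed Integer master seed for the plate.
#' @param n_ntc Number of NTC-LB control wells (>= 1).
#' @param n_no_primer Number of no-primer control wells.
#' @param control_protocol Protocol used for control wells.
#' @param thinning Thinning mode passed to the stochastic steps.
#' @return An object of class \code{plate_layout}: list with \code{wells}
#'   (each a list of \code{record} ([sample_record()]) and \code{well}
#'   ([droplet_well()])) and the recorded \code{seed}.
#' @export
simulate_plate <- function(samples, background_mean_per_ul = 1.5,
                           amp = amplitude_model(),
                           kinetics = extension_kinetics(),
                           seed = 1L, n_ntc = 3L, n_no_primer = 1L,
                           control_protocol = protocol_spec(cells_lysed = 0),
                           thinning = c("binomial", "expected")) {
  if (!is.list(samples) || length(samples) == 0L)
    stop("`samples` must be a non-empty list of sample descriptors",
         call. = FALSE)
  if (background_mean_per_ul < 0)
    stop("`background_mean_per_ul` must be >= 0", call. = FALSE)
  if (n_ntc < 1L)
    stop("a plate needs at least one NTC-LB control well", call. = FALSE)
  thinning <- match.arg(thinning)

  wells <- list()
  counter <- 0L
  emit <- function(record, well) {
    wells[[length(wells) + 1L]] <<- list(record = record, well = well)
  }
  sim_well <- function(molecules_pcr, protocol, well_id, role, no_primer = FALSE) {
    cap <- min(1, protocol$droplets_generated * protocol$droplet_volume_nl *
                 1e-3 / protocol$pcr_volume_ul)
    in_emulsion <- thin_count(molecules_pcr, cap, thinning)
    counts <- if (no_primer) integer(protocol$droplets_generated)
      else partition_into_droplets(in_emulsion, protocol)
    render_amplitudes(counts, amp, protocol, well_id = well_id, role = role,
                      true_molecule_count = molecules_pcr)
  }

  for (si in seq_along(samples)) {
    s <- samples[[si]]
    if (is.null(s$model) || is.null(s$protocol))
      stop("each sample descriptor needs `model` and `protocol`", call. = FALSE)
    nrep <- if (is.null(s$n_replicates)) 1L else as.integer(s$n_replicates)
    sid <- if (is.null(s$sample_id)) s$model$label else s$sample_id
    for (r in seq_len(nrep)) {
      counter <- counter + 1L
      set.seed(derive_seed(seed, counter))
      well_id <- sprintf("S%02d_R%02d", si, r)
      prods <- draw_cell_products(s$model, s$protocol$cells_lysed)
      ext <- simulate_extension(prods, s$protocol, kinetics,
                                thinning = thinning)
      aliquot_frac <- s$protocol$extension_into_pcr_ul /
        s$protocol$extension_volume_ul
      in_pcr <- thin_count(ext$molecules, aliquot_frac, thinning)
      bg <- if (background_mean_per_ul > 0)
        stats::rpois(1L, background_mean_per_ul * s$protocol$pcr_volume_ul)
      else 0L
      rec <- sample_record(sample_id = sid, well_id = well_id, role = "sample",
                           protocol = s$protocol,
                           dose = s$dose, timepoint = s$timepoint,
                           replicate = r)
      emit(rec, sim_well(in_pcr + bg, s$protocol, well_id, "sample"))
    }
  }
  for (j in seq_len(n_ntc)) {
    counter <- counter + 1L
    set.seed(derive_seed(seed, counter))
    well_id <- sprintf("NTC%02d", j)
    bg <- if (background_mean_per_ul > 0)
      stats::rpois(1L, background_mean_per_ul * control_protocol$pcr_volume_ul)
    else 0L
    rec <- sample_record(sample_id = "NTC-LB", well_id = well_id,
                         role = "ntc_lb", protocol = control_protocol,
                         replicate = j)
    emit(rec, sim_well(bg, control_protocol, well_id, "ntc_lb"))
  }
  for (j in seq_len(n_no_primer)) {
    counter <- counter + 1L
    set.seed(derive_seed(seed, counter))
    well_id <- sprintf("NP%02d", j)
    rec <- sample_record(sample_id = "no-primer", well_id = well_id,
                         role = "no_primer", protocol = control_protocol,
                         replicate = j)
    emit(rec, sim_well(0L, control_protocol, well_id, "no_primer",
                       no_primer = TRUE))
  }

  ids <- vapply(wells, function(w) w$record$well_id, character(1))
  stopifnot(!anyDuplicated(ids))
  structure(list(wells = wells, seed = as.integer(seed)),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  roles <- vapply(x$wells, function(w) w$record$role, character(1))
  cat(sprintf("Simulated plate: %d wells (%d sample, %d NTC-LB, %d no-primer), seed %d\n",
              length(x$wells), sum(roles == "sample"), sum(roles == "ntc_lb"),
              sum(roles == "no_primer"), x$seed))
  invisible(x)
}
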
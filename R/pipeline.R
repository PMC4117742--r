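# Plate-level bookkeeping: NTC background correction at the concentration
# level, scaling to total products, per-cell-equivalent normalization and
# positivity calling.

#' Subtract NTC-LB background from a sample concentration
#'
#' The mean of the plate's NTC-LB (no-template lysis-buffer control)
#' concentrations is subtracted from the sample's copies/ul before any
#' volume scaling; negative results are floored at zero and the floor is
#' flagged (the unfloored value is retained for diagnostics).
#'
#' @param sample_est A [estimate_concentration()] result or bare copies/ul.
#' @param ntc_estimates List of NTC-LB [estimate_concentration()] results (or
#'   numeric copies/ul values); at least one is required.
#' @return List with \code{corrected_copies_per_ul},
#'   \code{background_copies_per_ul} (the NTC mean), \code{floor_applied} and
#'   \code{unfloored_copies_per_ul}.
#' @export
background_correct <- function(sample_est, ntc_estimates) {
  cpul <- function(e) if (inherits(e, "concentration_estimate"))
    e$copies_per_ul else as.numeric(e)
  if (length(ntc_estimates) == 0L)
    stop("background correction needs at least one NTC-LB estimate on the plate",
         call. = FALSE)
  if (inherits(ntc_estimates, "concentration_estimate"))
    ntc_estimates <- list(ntc_estimates)
  bg <- mean(vapply(ntc_estimates, cpul, numeric(1)))
  raw <- cpul(sample_est)
  corrected <- raw - bg
  list(corrected_copies_per_ul = max(0, corrected),
       background_copies_per_ul = bg,
       floor_applied = corrected < 0,
       unfloored_copies_per_ul = corrected)
}

#' Per-cell-equivalent telomerase activity
#'
#' Scales the background-corrected concentration to total products
#' (\code{x pcr_volume_ul}) and normalizes by the record's cell equivalents.
#' Records with zero cell equivalents (controls) get \code{NA} per-cell
#' activity rather than zero — no cells were assayed, so per-cell activity is
#' not applicable.
#'
#' @param corrected_copies_per_ul Background-corrected concentration
#'   (molecules/ul of PCR).
#' @param rec A [sample_record()].
#' @return List with \code{total_products}, \code{cell_equivalents} and
#'   \code{per_cell_activity} (molecules/cell, \code{NA} when no cells).
#' @export
per_cell_activity <- function(corrected_copies_per_ul, rec) {
  stopifnot(inherits(rec, "sample_record"))
  total <- corrected_copies_per_ul * rec$pcr_volume_ul
  ce <- cell_equivalents(rec)
  list(total_products = total,
       cell_equivalents = ce,
       per_cell_activity = if (ce > 0) total / ce else NA_real_)
}

#' Call a sample positive for telomerase activity
#'
#' Default rule: positive when the sample's raw (uncorrected) copies/ul
#' exceeds \code{mean(NTC) + rule_k x SD(NTC)} over the plate's NTC-LB wells
#' (default \code{rule_k = 3}). With fewer than two NTC wells the SD is
#' undefined and the rule falls back to a CI comparison: positive when the
#' sample's CI lower bound exceeds the NTC mean (a notice is attached).
#'
#' @param raw_copies_per_ul Sample concentration before background
#'   correction, or a [estimate_concentration()] (whose CI enables the
#'   fallback rule).
#' @param ntc_estimates List of NTC-LB estimates (or numeric copies/ul).
#' @param rule_k SD multiplier (default 3).
#' @return List with \code{positive} (logical), \code{rule}, \code{rule_k},
#'   \code{ntc_mean}, \code{ntc_sd} and \code{threshold_copies_per_ul}.
#' @export
call_positive <- function(raw_copies_per_ul, ntc_estimates, rule_k = 3) {
  cpul <- function(e) if (inherits(e, "concentration_estimate"))
    e$copies_per_ul else as.numeric(e)
  if (length(ntc_estimates) == 0L)
    stop("positivity calling needs NTC-LB estimates", call. = FALSE)
  if (inherits(ntc_estimates, "concentration_estimate"))
    ntc_estimates <- list(ntc_estimates)
  ntc <- vapply(ntc_estimates, cpul, numeric(1))
  est <- raw_copies_per_ul
  raw <- cpul(est)
  if (length(ntc) >= 2L) {
    thr <- mean(ntc) + rule_k * stats::sd(ntc)
    list(positive = raw > thr, rule = "mean_plus_k_sd", rule_k = rule_k,
         ntc_mean = mean(ntc), ntc_sd = stats::sd(ntc),
         threshold_copies_per_ul = thr)
  } else {
    low <- if (inherits(est, "concentration_estimate")) est$ci_low_per_ul
      else raw
    message("fewer than 2 NTC wells: positivity falls back to the CI rule ",
            "(sample CI lower bound > NTC mean)")
    list(positive = low > mean(ntc), rule = "ci_lower_above_ntc_mean",
         rule_k = NA_real_, ntc_mean = mean(ntc), ntc_sd = NA_real_,
         threshold_copies_per_ul = mean(ntc))
  }
}

#' Process a plate from droplet amplitudes to activity results
#'
#' Runs the full analysis chain for every well of a plate:
#' control-anchored thresholding ([set_threshold()]), droplet counting,
#' Poisson-corrected concentration estimation, NTC-LB background
#' correction, scaling to total products, per-cell-equivalent
#' normalization and positivity calling. Wells with fewer read droplets
#' than \code{min_droplets} are flagged (\code{qc_pass = FALSE}) and
#' excluded from the plate's threshold/NTC summaries.
#'
#' @param plate A [simulate_plate()] result, or a list of
#'   \code{list(record =, well =)} pairs (e.g. from [read_plate_dir()]).
#' @param threshold_method,threshold_k Passed to [set_threshold()].
#' @param rule_k Positivity SD multiplier (see [call_positive()]).
#' @param min_droplets Minimum read droplets for a well to pass QC
#'   (default 10,000).
#' @param droplet_volume_nl Droplet volume used for the concentration
#'   estimates (default 0.85).
#' @param ci_method CI construction for [estimate_concentration()].
#' @return A data frame of class \code{activity_table} with one row per well
#'   (controls included, flagged by \code{role}) and columns for counts,
#'   concentrations, CI bounds, correction, totals, cell equivalents,
#'   per-cell activity and the positive call. Plate-level QC (threshold
#'   decision, NTC mean/SD, floor count) is attached as
#'   \code{attr(, "qc")}.
#' @export
process_plate <- function(plate,
                          threshold_method = "control_anchored",
                          threshold_k = 7, rule_k = 3,
                          min_droplets = 10000,
                          droplet_volume_nl = 0.85,
                          ci_method = "wilson") {
  wells <- if (inherits(plate, "plate_layout")) plate$wells else plate
  if (!is.list(wells) || length(wells) == 0L)
    stop("empty plate: nothing to process", call. = FALSE)
  roles <- vapply(wells, function(w) w$record$role, character(1))
  if (!any(roles == "ntc_lb"))
    stop("plate has no NTC-LB wells: background correction cannot proceed",
         call. = FALSE)

  qc_pass <- vapply(wells, function(w)
    length(w$well$amplitudes) >= min_droplets, logical(1))

  controls <- lapply(wells[roles != "sample" & qc_pass], `[[`, "well")
  thr <- if (threshold_method == "fixed")
    set_threshold(method = "fixed", value = threshold_k)
  else set_threshold(controls, method = threshold_method, k = threshold_k)

  ests <- lapply(wells, function(w) {
    cnt <- count_droplets(w$well, thr)
    estimate_concentration(cnt, droplet_volume_nl = droplet_volume_nl,
                           ci_method = ci_method)
  })

  ntc_ests <- ests[roles == "ntc_lb" & qc_pass]
  if (length(ntc_ests) == 0L)
    stop("no NTC-LB well passed droplet QC: background correction cannot proceed",
         call. = FALSE)

  rows <- lapply(seq_along(wells), function(i) {
    w <- wells[[i]]
    e <- ests[[i]]
    bc <- background_correct(e, ntc_ests)
    act <- per_cell_activity(bc$corrected_copies_per_ul, w$record)
    pos <- if (roles[i] == "sample")
      suppressMessages(call_positive(e, ntc_ests, rule_k = rule_k))
    else list(positive = NA)
    data.frame(
      sample_id = w$record$sample_id,
      well_id = w$record$well_id,
      role = roles[i],
      dose = w$record$dose,
      timepoint = w$record$timepoint,
      replicate = w$record$replicate,
      n_total = e$counts$n_total,
      n_positive = e$counts$n_positive,
      lambda_hat = e$lambda_hat,
      raw_copies_per_ul = e$copies_per_ul,
      ci_low_per_ul = e$ci_low_per_ul,
      ci_high_per_ul = e$ci_high_per_ul,
      background_copies_per_ul = bc$background_copies_per_ul,
      corrected_copies_per_ul = bc$corrected_copies_per_ul,
      unfloored_copies_per_ul = bc$unfloored_copies_per_ul,
      floor_applied = bc$floor_applied,
      total_products = act$total_products,
      cell_equivalents = act$cell_equivalents,
      per_cell_activity = act$per_cell_activity,
      positive_call = pos$positive,
      qc_pass = qc_pass[i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)

  ntc_cpul <- vapply(ntc_ests, `[[`, numeric(1), "copies_per_ul")
  attr(out, "qc") <- list(
    threshold = thr,
    ntc_mean_copies_per_ul = mean(ntc_cpul),
    ntc_sd_copies_per_ul = if (length(ntc_cpul) >= 2) stats::sd(ntc_cpul)
      else NA_real_,
    n_ntc = length(ntc_cpul),
    n_floor_applied = sum(out$floor_applied & out$role == "sample"),
    n_qc_fail = sum(!qc_pass),
    min_droplets = min_droplets,
    rule_k = rule_k
  )
  class(out) <- c("activity_table", "data.frame")
  out
}

#' @export
print.activity_table <- function(x, ...) {
  qc <- attr(x, "qc")
  cat(sprintf("ddTRAP activity table: %d wells (%d samples)\n",
              nrow(x), sum(x$role == "sample")))
  if (!is.null(qc)) {
    cat(sprintf("  threshold %.1f a.u.; NTC background %.2f copies/ul (n = %d); %d corrections floored; %d wells failed droplet QC\n",
                qc$threshold$threshold, qc$ntc_mean_copies_per_ul, qc$n_ntc,
                qc$n_floor_applied, qc$n_qc_fail))
  }
  print.data.frame(utils::head(as.data.frame(x)[, c("sample_id", "well_id", "role",
                                                    "n_positive", "raw_copies_per_ul",
                                                    "corrected_copies_per_ul",
                                                    "total_products",
                                                    "per_cell_activity",
                                                    "positive_call")], 10),
                   row.names = FALSE, digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... and %d more wells\n", nrow(x) - 10))
  invisible(x)
}
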
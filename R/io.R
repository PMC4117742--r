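# File formats and the end-to-end workflow. Amplitude files mirror the
# single-column per-well CSV exports of droplet readers: a header line
# "Amplitude" followed by one fluorescence value per droplet.

#' Write a well's amplitudes to a single-column file
#'
#' @param well A [droplet_well()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_amplitude_file <- function(well, path) {
  stopifnot(inherits(well, "droplet_well"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("Amplitude", sprintf("%.4f", well$amplitudes)), con)
  invisible(path)
}

#' Read a single-column amplitude export
#'
#' Accepts the dialect written by [write_amplitude_file()] (and, by
#' construction, single-column "Amplitude" CSV exports from droplet-reader
#' software): a header line \code{Amplitude} followed by one numeric value
#' per droplet. Trailing blank lines are ignored; any other malformed line
#' is reported with its line number.
#'
#' @param path File path.
#' @param well_id Well identifier to attach (default: file name).
#' @param role Well role (default \code{"sample"}).
#' @return A [droplet_well()].
#' @export
read_amplitude_file <- function(path, well_id = NULL, role = "sample") {
  if (!file.exists(path)) stop("no such amplitude file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L)
    stop("empty amplitude file: ", path, call. = FALSE)
  if (trimws(lines[1]) != "Amplitude")
    stop("line 1 of ", path, ": expected header 'Amplitude', found '",
         trimws(lines[1]), "'", call. = FALSE)
  body <- lines[-1]
  if (length(body) == 0L)
    stop(path, ": header but no amplitude rows", call. = FALSE)
  vals <- suppressWarnings(as.numeric(body))
  bad <- which(!is.finite(vals))
  if (length(bad))
    stop("non-numeric amplitude at line ", bad[1] + 1L, " of ", path,
         ": '", body[bad[1]], "'", call. = FALSE)
  if (is.null(well_id))
    well_id <- sub("\\.[^.]*$", "", basename(path))
  droplet_well(well_id = well_id, role = role, amplitudes = vals)
}

#' Write a simulated plate as amplitude files plus manifest and sample sheet
#'
#' One amplitude file per well, a plate manifest (\code{manifest.csv}:
#' well_id, role, file, true_molecule_count) and a sample sheet
#' (\code{samples.csv}) holding every [sample_record()] field.
#'
#' @param plate A [simulate_plate()] result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_plate_dir <- function(plate, dir) {
  stopifnot(inherits(plate, "plate_layout"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(plate$wells, function(w) {
    f <- paste0(w$record$well_id, "_amplitude.csv")
    write_amplitude_file(w$well, file.path(dir, f))
    data.frame(well_id = w$record$well_id, role = w$record$role, file = f,
               true_molecule_count = w$well$true_molecule_count,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  sheet <- do.call(rbind, lapply(plate$wells, function(w) {
    r <- w$record
    data.frame(sample_id = r$sample_id, well_id = r$well_id, role = r$role,
               cells_lysed = r$cells_lysed,
               lysis_volume_ul = r$lysis_volume_ul,
               lysate_into_extension_ul = r$lysate_into_extension_ul,
               extension_volume_ul = r$extension_volume_ul,
               extension_into_pcr_ul = r$extension_into_pcr_ul,
               pcr_volume_ul = r$pcr_volume_ul,
               single_step = r$single_step,
               dose = r$dose, timepoint = r$timepoint,
               replicate = r$replicate, stringsAsFactors = FALSE)
  }))
  utils::write.csv(sheet, file.path(dir, "samples.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a plate directory (manifest + sample sheet + amplitude files)
#'
#' Reconstructs the \code{list(record =, well =)} structure consumed by
#' [process_plate()] from a directory written by [write_plate_dir()] (or
#' assembled by hand around instrument exports).
#'
#' @param dir Directory holding \code{manifest.csv}, \code{samples.csv} and
#'   the amplitude files the manifest names.
#' @return List of \code{list(record =, well =)} pairs.
#' @export
read_plate_dir <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  ss_path <- file.path(dir, "samples.csv")
  if (!file.exists(mf_path)) stop("no manifest.csv in ", dir, call. = FALSE)
  if (!file.exists(ss_path)) stop("no samples.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  sheet <- utils::read.csv(ss_path, stringsAsFactors = FALSE)
  if (anyDuplicated(manifest$well_id))
    stop("duplicate well_ids in manifest", call. = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    s <- sheet[sheet$well_id == m$well_id, ]
    if (nrow(s) != 1L)
      stop("well ", m$well_id, " missing from samples.csv", call. = FALSE)
    fp <- file.path(dir, m$file)
    well <- read_amplitude_file(fp, well_id = m$well_id, role = m$role)
    well$true_molecule_count <- if ("true_molecule_count" %in% names(m))
      m$true_molecule_count else NA_real_
    rec <- sample_record(
      sample_id = s$sample_id, well_id = s$well_id, role = s$role,
      cells_lysed = s$cells_lysed, lysis_volume_ul = s$lysis_volume_ul,
      lysate_into_extension_ul = s$lysate_into_extension_ul,
      extension_volume_ul = s$extension_volume_ul,
      extension_into_pcr_ul = s$extension_into_pcr_ul,
      pcr_volume_ul = s$pcr_volume_ul, single_step = s$single_step,
      dose = if (is.na(s$dose)) NULL else s$dose,
      timepoint = if (is.na(s$timepoint)) NULL else s$timepoint,
      replicate = if (is.na(s$replicate)) NULL else s$replicate)
    list(record = rec, well = well)
  })
}

# Known run-config keys and their defaults.
default_run_config <- function() {
  list(
    seed = 1L,
    background_mean_per_ul = 1.5,
    droplet_volume_nl = 0.85,
    droplets_generated = 20000L,
    droplets_read = 17000L,
    threshold_method = "control_anchored",
    threshold_k = 7,
    rule_k = 3,
    min_droplets = 10000L,
    ci_method = "wilson",
    n_ntc = 3L,
    n_no_primer = 1L,
    n_single_cells = 78L,
    dilution_cell_eq = c(100, 50, 25, 12.5, 6.25),
    n_dilution_series = 3L,
    doses_uM = c(0, 0.125, 0.25, 0.5, 1, 3),
    ic50_uM = 0.2,
    hill = 1,
    dose_cv = 0.09,
    n_dose_replicates = 9L,
    timepoints_h = c(0, 6, 24, 48),
    n_timecourse_pairs = 4L,
    out_dir = "ddtrap_out",
    verbosity = 1L
  )
}

#' Read a run configuration file
#'
#' Loads a YAML (or flat \code{key: value}) configuration, fills unset keys
#' from the package defaults and rejects unknown keys. Every value is echoed
#' into the run log by [run_end_to_end()].
#'
#' @param path YAML config path; \code{NULL} returns the defaults.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(user)] <- user
  cfg
}

# Small deterministic FNV-1a hash of the deparsed config, for run logs and
# output-file headers.
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

write_output_csv <- function(df, path, cfg) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# ddtrap config_hash=%s seed=%d", config_hash(cfg),
                     as.integer(cfg$seed)), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

activity_csv_columns <- function(tab) {
  df <- as.data.frame(tab)
  qc <- attr(tab, "qc")
  if (!is.null(qc)) df$amplitude_threshold <- qc$threshold$threshold
  df
}

#' Run a complete in-silico assay scenario
#'
#' Simulates a plate for the chosen scenario, writes its amplitude files,
#' re-reads and processes them through the quantification pipeline and runs
#' the scenario's analysis, writing all outputs as CSV plus a run log. Reruns
#' with the same configuration are byte-identical.
#'
#' Scenarios: \code{dilution_series} (replicate limiting-dilution series, CV
#' table + linearity fit), \code{single_cells} (one-step lysis-extension
#' wells, positivity summary), \code{dose_response} (inhibitor doses, 4PL
#' IC50 fit), \code{timecourse} (paired stimulation time course),
#' \code{cell_panel} (telomerase-positive vs -negative presets).
#'
#' @param config Config list from [read_run_config()] (or \code{NULL} for
#'   defaults).
#' @param scenario One of the scenario names above.
#' @param out_dir Output directory; overrides the config's.
#' @return Invisibly, a list with the activity table and the scenario's
#'   analysis object(s); files are written under \code{out_dir}.
#' @export
run_end_to_end <- function(config = NULL,
                           scenario = c("dilution_series", "single_cells",
                                        "dose_response", "timecourse",
                                        "cell_panel"),
                           out_dir = NULL) {
  scenario <- match.arg(scenario)
  cfg <- if (is.null(config)) default_run_config() else config
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- c(
    sprintf("ddtrap run: scenario=%s", scenario),
    sprintf("package version: %s",
            as.character(utils::packageVersion("ddtrap"))),
    sprintf("config_hash: %s", config_hash(cfg)),
    paste0("config: ", names(cfg), " = ",
           vapply(cfg, function(v) paste(format(v), collapse = ","),
                  character(1)))
  )

  kin <- extension_kinetics()
  amp <- amplitude_model()
  proto_for <- function(cells) protocol_spec(
    cells_lysed = cells,
    droplet_volume_nl = cfg$droplet_volume_nl,
    droplets_generated = cfg$droplets_generated,
    droplets_read = cfg$droplets_read)

  samples <- switch(scenario,
    dilution_series = {
      # cells_lysed chosen so the standard chain yields the target cell eq:
      # cell_eq = cells / 40 / 50 * 2  =>  cells = cell_eq * 1000
      unlist(lapply(seq_len(cfg$n_dilution_series), function(s)
        lapply(cfg$dilution_cell_eq, function(ce)
          list(model = cell_preset("hela_bulk"), protocol = proto_for(ce * 1000),
               n_replicates = 1L, sample_id = sprintf("dil%g_series%d", ce, s)))),
        recursive = FALSE)
    },
    single_cells = {
      lapply(seq_len(cfg$n_single_cells), function(i)
        list(model = cell_preset("hela_single_cell"),
             protocol = single_cell_protocol(
               droplet_volume_nl = cfg$droplet_volume_nl,
               droplets_generated = cfg$droplets_generated,
               droplets_read = cfg$droplets_read),
             n_replicates = 1L, sample_id = sprintf("cell%03d", i)))
    },
    dose_response = {
      base <- cell_preset("hela_bulk")
      unlist(lapply(cfg$doses_uM, function(dd) {
        inhib <- four_pl(dd, 1, 0, cfg$ic50_uM, cfg$hill)
        m <- cell_model(sprintf("hela_dose_%g", dd), base$fraction_active,
                        base$mean_products_per_active_cell * inhib,
                        base$dispersion)
        lapply(seq_len(cfg$n_dose_replicates), function(r)
          list(model = m, protocol = proto_for(50000), n_replicates = 1L,
               sample_id = sprintf("dose%g_r%d", dd, r), dose = dd))
      }), recursive = FALSE)
    },
    timecourse = {
      base <- cell_preset("hela_bulk")
      # transient activity burst: low baseline, peak at 6 h persisting to
      # 24 h, return to baseline by 48 h
      lvl <- c(`0` = 0.1, `6` = 1, `24` = 0.8, `48` = 0.12)
      unlist(lapply(cfg$timepoints_h, function(tp) {
        f <- lvl[as.character(tp)]
        m <- cell_model(sprintf("pbmc_%gh", tp), base$fraction_active,
                        base$mean_products_per_active_cell * f,
                        base$dispersion)
        lapply(seq_len(cfg$n_timecourse_pairs), function(r)
          list(model = m, protocol = proto_for(50000), n_replicates = 1L,
               sample_id = sprintf("t%g_r%d", tp, r), timepoint = tp))
      }), recursive = FALSE)
    },
    cell_panel = {
      presets <- c("hela_bulk", "telomerase_negative")
      unlist(lapply(presets, function(p)
        list(list(model = cell_preset(p), protocol = proto_for(50000),
                  n_replicates = 3L, sample_id = p))), recursive = FALSE)
    }
  )

  plate <- simulate_plate(samples,
                          background_mean_per_ul = cfg$background_mean_per_ul,
                          amp = amp, kinetics = kin, seed = cfg$seed,
                          n_ntc = cfg$n_ntc, n_no_primer = cfg$n_no_primer)
  plate_dir <- file.path(out_dir, "plate")
  write_plate_dir(plate, plate_dir)
  wells <- read_plate_dir(plate_dir)
  tab <- process_plate(wells,
                       threshold_method = cfg$threshold_method,
                       threshold_k = cfg$threshold_k, rule_k = cfg$rule_k,
                       min_droplets = cfg$min_droplets,
                       droplet_volume_nl = cfg$droplet_volume_nl,
                       ci_method = cfg$ci_method)
  write_output_csv(activity_csv_columns(tab),
                   file.path(out_dir, "results.csv"), cfg)

  analyses <- list()
  samp <- tab[tab$role == "sample", , drop = FALSE]
  if (scenario == "dilution_series") {
    cvt <- cv_table(tab)
    fit <- fit_dilution_series(samp$cell_equivalents, samp$total_products)
    write_output_csv(cvt, file.path(out_dir, "cv_table.csv"), cfg)
    write_output_csv(data.frame(slope = fit$slope, intercept = fit$intercept,
                                r_squared = fit$r_squared,
                                n_points = fit$n_points),
                     file.path(out_dir, "dilution_fit.csv"), cfg)
    analyses <- list(cv_table = cvt, dilution_fit = fit)
  } else if (scenario == "single_cells") {
    sc <- summarize_single_cells(tab)
    write_output_csv(data.frame(n_cells = sc$n_cells,
                                n_positive = sc$n_positive,
                                positive_percent = sc$positive_percent,
                                mean_activity_all = sc$mean_activity_all,
                                mean_activity_positive = sc$mean_activity_positive,
                                sem = sc$sem),
                     file.path(out_dir, "single_cell_summary.csv"), cfg)
    analyses <- list(single_cell_summary = sc)
  } else if (scenario == "dose_response") {
    ctrl <- samp[samp$dose == 0, , drop = FALSE]
    rel <- relative_activity(samp, ctrl)
    fit <- fit_ic50(samp$dose, rel)
    write_output_csv(data.frame(top = fit$top, bottom = fit$bottom,
                                hill_slope = fit$hill_slope, ic50 = fit$ic50,
                                converged = fit$converged,
                                method = fit$method),
                     file.path(out_dir, "ic50_fit.csv"), cfg)
    analyses <- list(ic50_fit = fit, relative_activity = rel)
  } else if (scenario == "timecourse") {
    tc <- compare_timepoints(tab, baseline = "0")
    write_output_csv(tc, file.path(out_dir, "timecourse.csv"), cfg)
    analyses <- list(timecourse = tc)
  } else if (scenario == "cell_panel") {
    panel <- stats::aggregate(
      cbind(total_products, per_cell_activity) ~ sample_id, data = samp, FUN = mean)
    write_output_csv(panel, file.path(out_dir, "cell_panel.csv"), cfg)
    analyses <- list(cell_panel = panel)
  }

  qc <- attr(tab, "qc")
  log_lines <- c(log_lines,
                 sprintf("threshold: %.4f a.u.", qc$threshold$threshold),
                 sprintf("ntc mean: %.4f copies/ul over %d wells",
                         qc$ntc_mean_copies_per_ul, qc$n_ntc),
                 sprintf("floors applied: %d; QC failures: %d",
                         qc$n_floor_applied, qc$n_qc_fail))
  writeLines(log_lines, log_path)
  invisible(c(list(results = tab, config = cfg, out_dir = out_dir), analyses))
}
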
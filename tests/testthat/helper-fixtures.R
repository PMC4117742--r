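# Shared fixtures: small, well-separated synthetic wells built in code.

# Amplitude model with bands far apart relative to their SDs, so any
# between-band threshold classifies droplets perfectly.
separable_amp <- function() {
  amplitude_model(mu_negative = 1000, sd_negative = 50,
                  mu_positive = 9000, sd_positive = 100, rain_fraction = 0)
}

# Reduced-droplet protocol for fast unit tests (not used where the full
# 17,000-droplet geometry matters).
small_protocol <- function(...) {
  protocol_spec(droplets_generated = 2000, droplets_read = 1700, ...)
}

# A droplet well with exactly known amplitudes.
fixed_well <- function(amplitudes, well_id = "W1", role = "sample") {
  droplet_well(well_id = well_id, role = role, amplitudes = amplitudes)
}

# Numeric vector with exactly the requested mean and sample SD.
vector_with_moments <- function(mean, sd, n = 100) {
  x <- stats::rnorm(n)
  x <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * x
}

# Simulate one plate of single-cell wells and process it.
single_cell_run <- function(n_cells, seed, n_ntc = 8) {
  sc <- lapply(seq_len(n_cells), function(i)
    list(model = cell_preset("hela_single_cell"),
         protocol = single_cell_protocol(),
         n_replicates = 1L, sample_id = sprintf("cell%03d", i)))
  plate <- simulate_plate(sc, seed = seed, n_ntc = n_ntc)
  process_plate(plate)
}

# Simulate replicate limiting-dilution series and process them.
dilution_run <- function(seed, cell_eq = c(100, 50, 25, 12.5, 6.25),
                         n_series = 3) {
  samples <- unlist(lapply(seq_len(n_series), function(s)
    lapply(cell_eq, function(ce)
      list(model = cell_preset("hela_bulk"),
           protocol = protocol_spec(cells_lysed = ce * 1000),
           n_replicates = 1L,
           sample_id = sprintf("dil%g_s%d", ce, s)))),
    recursive = FALSE)
  plate <- simulate_plate(samples, seed = seed)
  process_plate(plate)
}
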
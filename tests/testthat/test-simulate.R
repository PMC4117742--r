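test_that("per-cell product draws follow the zero-inflated mixture", {
  # negative preset: every cell inactive
  neg <- draw_cell_products(cell_preset("telomerase_negative"), 100, seed = 1)
  expect_identical(neg, integer(100))
  expect_error(draw_cell_products(cell_preset("hela_bulk"), -1), "count")
  expect_identical(draw_cell_products(cell_preset("hela_bulk"), 0, seed = 1),
                   integer(0))

  # active-cell mean recovers the preset mean within 3 standard errors
  m <- cell_preset("hela_single_cell")
  x <- draw_cell_products(m, 10000, seed = 42)
  act <- x[x > 0]
  se <- sd(act) / sqrt(length(act))
  expect_lt(abs(mean(act) - m$mean_products_per_active_cell), 3 * se)
  # zero fraction near 1 - fraction_active (zeros from NB itself are rare)
  expect_lt(abs(mean(x == 0) - (1 - m$fraction_active)), 0.02)
})

test_that("infinite dispersion reduces to the Poisson limit", {
  m <- cell_model("poisson_limit", fraction_active = 1,
                  mean_products_per_active_cell = 5, dispersion = Inf)
  x <- draw_cell_products(m, 50000, seed = 7)
  # Poisson: variance equals the mean; compare against plain Poisson draws
  set.seed(7000)
  ref <- rpois(50000, 5)
  expect_lt(abs(var(x) - 5), 3 * sd((ref - 5)^2) / sqrt(50000))
  expect_lt(abs(mean(x) - 5), 3 * sqrt(5 / 50000))
})

test_that("extension applies lysate thinning and kinetic normalization", {
  proto <- protocol_spec()
  kin <- extension_kinetics()
  ext0 <- simulate_extension(integer(100), proto, kin, seed = 1)
  expect_identical(ext0$molecules, 0L)

  # 40-minute extension has kinetic scale exactly 1
  ext <- simulate_extension(rep(3L, 1000), proto, kin, seed = 2)
  expect_identical(ext$scale, 1)

  # kinetic scale is monotone in duration
  scales <- vapply(c(10, 20, 40, 80, 120), function(tm) {
    p <- protocol_spec(extension_minutes = tm)
    simulate_extension(rep(1L, 10), p, kin, seed = 3, thinning = "expected")$scale
  }, numeric(1))
  expect_true(all(diff(scales) > 0))
  expect_equal(scales[3], 1)

  # expected-mode thinning: 1/40 of cells, scale 1
  exp_mode <- simulate_extension(rep(10L, 40000), proto, kin,
                                 thinning = "expected")
  expect_identical(exp_mode$cells_in_extension, 1000L)
  expect_identical(exp_mode$molecules, 10000L)
  expect_equal(exp_mode$concentration_per_ul, 10000 / 50)
})

test_that("thinning composition matches the dilution-chain expectation", {
  # expected molecules in the PCR = cells x (1/40) x mean x scale x (2/50)
  proto <- protocol_spec(cells_lysed = 200000)
  kin <- extension_kinetics()
  m <- cell_model("flat", 1, 20, dispersion = Inf)
  reps <- vapply(1:40, function(s) {
    prods <- draw_cell_products(m, proto$cells_lysed, seed = 1000 + s)
    ext <- simulate_extension(prods, proto, kin, seed = 2000 + s)
    rbinom(1, ext$molecules,
           proto$extension_into_pcr_ul / proto$extension_volume_ul)
  }, numeric(1))
  expected <- 200000 * (1 / 40) * 20 * 1 * (2 / 50)
  expect_lt(abs(mean(reps) - expected), 3 * sd(reps) / sqrt(length(reps)))
})

test_that("droplet partitioning conserves molecules for any seed", {
  proto <- small_protocol()
  for (s in 1:25) {
    set.seed(s)
    mols <- sample(0:5000, 1)
    counts <- partition_into_droplets(mols, proto, seed = s)
    expect_identical(sum(counts), mols)
    expect_length(counts, proto$droplets_generated)
  }
  expect_identical(partition_into_droplets(0, proto, seed = 1),
                   integer(proto$droplets_generated))
  expect_error(partition_into_droplets(-1, proto), ">= 0")
})

test_that("per-droplet occupancy approaches the Poisson law for sparse loads", {
  proto <- protocol_spec(droplets_generated = 100000, droplets_read = 100000)
  counts <- partition_into_droplets(10000, proto, seed = 99)
  obs <- tabulate(pmin(counts, 3) + 1L, nbins = 4L)  # bins 0,1,2,3+
  lam <- 10000 / 100000
  p <- c(dpois(0:2, lam), ppois(2, lam, lower.tail = FALSE))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.001)
  # empty fraction near the closed form exp(-lambda)
  expect_lt(abs(mean(counts == 0) - exp(-lam)), 0.005)
})

test_that("amplitude rendering separates occupancy classes and subsamples", {
  amp <- separable_amp()
  proto <- small_protocol()

  # all-empty input: every amplitude from the negative band
  w0 <- render_amplitudes(integer(proto$droplets_generated), amp, proto,
                          seed = 4)
  thr <- amp$mu_negative + 5 * amp$sd_negative
  expect_identical(sum(w0$amplitudes > thr), 0L)
  expect_length(w0$amplitudes, proto$droplets_read)

  # well-separated bands: any between-band threshold recovers ground truth
  counts <- partition_into_droplets(300, proto, seed = 5)
  w <- render_amplitudes(counts, amp, proto, seed = 5)
  called <- w$amplitudes > 5000
  expect_identical(called, w$occupied)

  # no subsampling when every generated droplet is read
  pfull <- protocol_spec(droplets_generated = 2000, droplets_read = 2000)
  wf <- render_amplitudes(integer(2000), amp, pfull, seed = 6)
  expect_length(wf$amplitudes, 2000L)

  expect_error(render_amplitudes(integer(10), amp, proto), "length")
})

test_that("rain draws intermediate amplitudes for some occupied droplets", {
  amp <- amplitude_model(mu_negative = 1000, sd_negative = 50,
                         mu_positive = 9000, sd_positive = 100,
                         rain_fraction = 0.3)
  proto <- small_protocol()
  counts <- rep(1L, proto$droplets_generated)
  w <- render_amplitudes(counts, amp, proto, seed = 8)
  mid <- w$amplitudes > 2000 & w$amplitudes < 8000
  expect_gt(mean(mid), 0.2)
  expect_lt(mean(mid), 0.4)
})

test_that("simulated plates carry controls and reproduce bit-for-bit", {
  samples <- list(list(model = cell_preset("telomerase_negative"),
                       protocol = small_protocol(cells_lysed = 1000),
                       n_replicates = 2))
  p1 <- simulate_plate(samples, seed = 31, n_ntc = 3,
                       control_protocol = small_protocol(cells_lysed = 0))
  p2 <- simulate_plate(samples, seed = 31, n_ntc = 3,
                       control_protocol = small_protocol(cells_lysed = 0))
  expect_identical(p1, p2)
  roles <- vapply(p1$wells, function(w) w$record$role, character(1))
  expect_identical(sum(roles == "ntc_lb"), 3L)
  expect_identical(p1$seed, 31L)
  expect_error(simulate_plate(list(), seed = 1), "non-empty")
  expect_error(simulate_plate(samples, background_mean_per_ul = -1), ">= 0")
  expect_error(simulate_plate(samples, n_ntc = 0), "NTC-LB")
})

test_that("NTC wells carry Poisson background at mean x PCR volume", {
  # background 1.5 molecules/ul x 20 ul PCR = Poisson mean 30 per NTC well
  samples <- list(list(model = cell_preset("telomerase_negative"),
                       protocol = protocol_spec(cells_lysed = 0),
                       n_replicates = 1))
  p <- simulate_plate(samples, background_mean_per_ul = 1.5, seed = 17,
                      n_ntc = 60, n_no_primer = 0)
  ntc_truth <- vapply(p$wells, function(w)
    if (w$record$role == "ntc_lb") w$well$true_molecule_count else NA_real_,
    numeric(1))
  ntc_truth <- ntc_truth[!is.na(ntc_truth)]
  expect_lt(abs(mean(ntc_truth) - 30), 3 * sqrt(30 / 60))
  expect_lt(abs(var(ntc_truth) - 30), 25)  # Poisson: variance == mean
})

test_that("zero background makes negative samples and NTCs indistinguishable", {
  samples <- list(list(model = cell_preset("telomerase_negative"),
                       protocol = protocol_spec(cells_lysed = 50000),
                       n_replicates = 3))
  p <- simulate_plate(samples, background_mean_per_ul = 0, seed = 23)
  truth <- vapply(p$wells, function(w) w$well$true_molecule_count, numeric(1))
  roles <- vapply(p$wells, function(w) w$record$role, character(1))
  expect_true(all(truth[roles != "no_primer"] == 0))
})
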
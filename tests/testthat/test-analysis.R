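test_that("CV arithmetic reproduces printed replicate statistics", {
  # replicate-table rows: CV% = SD/mean x 100 to 2 decimals
  expect_equal(cv_percent(136.6, 1587.3), 8.61)
  expect_equal(cv_percent(106.1, 378.7), 28.02)
  expect_true(is.na(cv_percent(1, 0)))
})

test_that("cv_table matches an independent two-pass computation", {
  set.seed(5)
  df <- data.frame(
    cell_equivalents = rep(c(100, 50, 25), each = 4),
    total_products = rexp(12, 1 / 500)
  )
  tab <- cv_table(df)
  for (g in unique(df$cell_equivalents)) {
    v <- df$total_products[df$cell_equivalents == g]
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1))
    row <- tab[tab$group_label == as.character(g), ]
    expect_equal(row$mean_total_products, m)
    expect_equal(row$sd_total_products, s)
    expect_equal(row$cv_percent, round(s / m * 100, 2))
  }
  # identical replicates: CV exactly 0
  same <- data.frame(cell_equivalents = rep(10, 3), total_products = rep(7, 3))
  expect_equal(cv_table(same)$cv_percent, 0)
  # singleton group flagged with undefined CV
  one <- data.frame(cell_equivalents = c(1, 1, 2),
                    total_products = c(5, 6, 7))
  t1 <- cv_table(one)
  expect_true(is.na(t1$cv_percent[t1$group_label == "2"]))
  expect_identical(t1$n_replicates[t1$group_label == "2"], 1L)
})

test_that("dilution fits are exact on collinear data and scale-equivariant", {
  x <- c(100, 50, 25, 12.5, 6.25)
  y <- 3 * x + 2
  f <- fit_dilution_series(x, y)
  expect_equal(f$r_squared, 1)
  expect_equal(f$slope, 3)
  expect_equal(f$intercept, 2)

  set.seed(9)
  y2 <- 3 * x + rnorm(5, 0, 5)
  f1 <- fit_dilution_series(x, y2)
  f2 <- fit_dilution_series(x, 10 * y2)
  expect_equal(f2$slope, 10 * f1$slope)
  expect_equal(f2$r_squared, f1$r_squared)

  expect_error(fit_dilution_series(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("single-cell summaries count positives and flag empty cases", {
  df <- data.frame(cell_equivalents = rep(1, 78),
                   total_products = c(rep(60, 57), rep(0, 21)),
                   positive_call = c(rep(TRUE, 57), rep(FALSE, 21)))
  s <- summarize_single_cells(df)
  expect_identical(s$n_positive, 57L)
  expect_identical(s$positive_percent, 73)
  expect_equal(s$mean_activity_positive, 60)

  # order invariance
  s2 <- summarize_single_cells(df[sample(nrow(df)), ])
  expect_equal(s2$positive_fraction, s$positive_fraction)

  neg <- data.frame(cell_equivalents = rep(1, 5), total_products = rep(0, 5),
                    positive_call = rep(FALSE, 5))
  sneg <- summarize_single_cells(neg)
  expect_identical(sneg$positive_percent, 0)
  expect_true(is.na(sneg$mean_activity_positive))

  expect_error(summarize_single_cells(df[0, ]), "no single-cell")
  df$cell_equivalents[1] <- 50
  expect_error(summarize_single_cells(df), "cell_equivalents = 1")
})

test_that("single-cell positive fraction tracks the generator preset", {
  tab <- single_cell_run(78, seed = 13)
  s <- summarize_single_cells(tab)
  expect_identical(s$n_cells, 78L)
  # binomial 95% bounds around fraction_active = 0.73 at n = 78
  bounds <- qbinom(c(0.025, 0.975), 78, 0.73) / 78
  expect_gte(s$positive_fraction, bounds[1])
  expect_lte(s$positive_fraction, bounds[2])
})

test_that("relative activity is the ratio to the control mean", {
  ctrl <- c(100, 110, 90)
  expect_equal(relative_activity(ctrl, ctrl), ctrl / 100)
  expect_equal(relative_activity(c(0, 0), ctrl), c(0, 0))
  expect_error(relative_activity(c(1, 2), c(0, 0)), "positive")

  # simulated half-activity samples: mean ratio about 0.5
  set.seed(10)
  treated <- rnorm(200, 50, 5)
  control <- rnorm(200, 100, 10)
  expect_lt(abs(mean(relative_activity(treated, control)) - 0.5), 0.02)
})

test_that("relative activity reproduces a simulated fold change", {
  # two presets whose activity differs 8-fold; the measured ratio
  # recovers the generator ratio within Monte-Carlo error
  hi <- cell_preset("hela_bulk")
  lo <- cell_model("low_line", hi$fraction_active,
                   hi$mean_products_per_active_cell / 8, hi$dispersion)
  samples <- list(
    list(model = hi, protocol = protocol_spec(cells_lysed = 50000),
         n_replicates = 6, sample_id = "high"),
    list(model = lo, protocol = protocol_spec(cells_lysed = 50000),
         n_replicates = 6, sample_id = "low"))
  tab <- process_plate(simulate_plate(samples, seed = 29))
  samp <- tab[tab$role == "sample", ]
  ratio <- mean(samp$total_products[samp$sample_id == "high"]) /
    mean(samp$total_products[samp$sample_id == "low"])
  expect_lt(abs(ratio - 8) / 8, 0.2)
})

test_that("noiseless 4PL data invert to the generating parameters", {
  doses <- c(0, 0.125, 0.25, 0.5, 1, 3)
  d <- simulate_relative_activity(doses, ic50 = 0.2, hill = 1,
                                  n_replicates = 3, cv = 0, seed = 1)
  f <- fit_ic50(d$dose_uM, d$relative_activity)
  expect_true(f$converged)
  expect_equal(f$ic50, 0.2, tolerance = 1e-6)
  expect_equal(f$top, 1, tolerance = 1e-6)
  expect_equal(f$hill_slope, 1, tolerance = 1e-4)
})

test_that("the 4PL fit recovers parameters across random replicate sets", {
  doses <- c(0, 0.125, 0.25, 0.5, 1, 3)
  rec <- vapply(1:25, function(s) {
    d <- simulate_relative_activity(doses, ic50 = 0.2, hill = 1,
                                    n_replicates = 9, cv = 0.09, seed = s)
    f <- fit_ic50(d$dose_uM, d$relative_activity)
    expect_true(f$converged)
    c(f$ic50, f$top, f$bottom)
  }, numeric(3))
  expect_true(all(abs(rec[1, ] - 0.2) / 0.2 < 0.15))
  expect_true(all(abs(rec[2, ] - 1) < 0.1))
  expect_true(all(abs(rec[3, ]) < 0.1))
})

test_that("flat dose-response data are flagged non-convergent", {
  set.seed(3)
  doses <- c(0, 0.125, 0.25, 0.5, 1, 3)
  d <- data.frame(dose_uM = rep(doses, each = 4),
                  relative_activity = 1 + rnorm(24, 0, 0.02))
  f <- fit_ic50(d$dose_uM, d$relative_activity)
  expect_false(f$converged)
  expect_identical(f$method, "interpolation")
  expect_error(fit_ic50(c(0, 1), c(1, 0.5)), "4 dose levels")
})

test_that("paired time-course tests behave at the edges and under effects", {
  # identical paired values: t = 0, p = 1
  df <- data.frame(timepoint = rep(c("0", "6"), each = 4),
                   replicate = rep(1:4, 2),
                   total_products = rep(c(10, 12, 9, 11), 2))
  tc <- compare_timepoints(df, baseline = "0")
  row6 <- tc[tc$timepoint == "6", ]
  expect_equal(row6$t_statistic, 0)
  expect_equal(row6$p_value, 1)

  # a +5 SD burst at 6 h is detected at p < 0.05 with 4 pairs
  set.seed(21)
  base <- rnorm(4, 100, 10)
  burst <- base + 50 + rnorm(4, 0, 10)
  df2 <- data.frame(timepoint = rep(c("0", "6"), each = 4),
                    replicate = rep(1:4, 2),
                    total_products = c(base, burst))
  tc2 <- compare_timepoints(df2, baseline = "0")
  expect_lt(tc2$p_value[tc2$timepoint == "6"], 0.05)

  # bonferroni flag scales the p-values
  tc3 <- compare_timepoints(df2, baseline = "0", adjust = "bonferroni")
  expect_equal(tc3$p_adjusted[tc3$timepoint == "6"],
               min(1, tc2$p_value[tc2$timepoint == "6"] * 1))

  # a single pair is insufficient
  df3 <- data.frame(timepoint = c("0", "6"), replicate = c(1, 1),
                    total_products = c(1, 2))
  expect_error(compare_timepoints(df3, baseline = "0"), "2 replicate pairs")

  # unmatched replicate structure is a pairing error
  df4 <- df2
  df4$replicate[df4$timepoint == "6"] <- c(1, 2, 3, 9)
  expect_error(compare_timepoints(df4, baseline = "0"), "pair")
})
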
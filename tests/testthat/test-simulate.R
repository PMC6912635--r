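sch_dd <- ld_dd_schedule(16, 8, ld_days = 4, dd_days = 10)
tpl_s <- waveform_template(0, 5, 13)

test_that("waveform hits its markers and validates its geometry", {
  expect_equal(template_rate(tpl_s, 0), tpl_s$baseline_rate)    # onset
  expect_equal(template_rate(tpl_s, 5), tpl_s$peak_rate)        # peak
  expect_equal(template_rate(tpl_s, 13), tpl_s$baseline_rate)   # offset
  expect_equal(template_rate(tpl_s, 20), tpl_s$baseline_rate)   # night
  # wrapping template: active across midnight
  w <- waveform_template(21.5, 2.5, 8)
  expect_equal(template_rate(w, 2.5), w$peak_rate)
  expect_gt(template_rate(w, 23), w$baseline_rate)
  expect_error(waveform_template(5, 5, 13), "ordered")
  expect_error(waveform_template(0, 5, 13, peak_rate = 0.05), "exceed")
})

test_that("arrhythmic individuals emit the template's constant time-average", {
  p <- individual_params(24, rhythmic = FALSE, template = tpl_s)
  r <- rate_at(p, sch_dd, c(1, 500, 7000, 20000))
  expect_equal(r, rep(template_mean_rate(tpl_s), 4))
  # analytic mean: baseline + amp/2 * active/24
  expect_equal(template_mean_rate(tpl_s),
               tpl_s$baseline_rate +
                 (tpl_s$peak_rate - tpl_s$baseline_rate) / 2 * 13 / 24)
})

test_that("rate is entrained under LD and free-runs with period tau in DD", {
  sch_ld <- ld_schedule(16, 8, n_days = 6)
  p24 <- individual_params(24, template = tpl_s)
  t <- seq_len(2 * 1440)
  expect_equal(rate_at(p24, sch_ld, t), rate_at(p24, sch_ld, t + 1440))
  # tau = 24 in DD: exact 1440-min periodicity
  tdd <- dd_onset_minute(sch_dd) + seq_len(1440)
  expect_equal(rate_at(p24, sch_dd, tdd), rate_at(p24, sch_dd, tdd + 1440))
  # tau = 26.7 h = 1602 min: period in DD is exactly 1602 min, and the
  # subjective peak drifts +2.7 h of clock time per cycle
  p <- individual_params(26.7, template = tpl_s)
  expect_equal(rate_at(p, sch_dd, tdd), rate_at(p, sch_dd, tdd + 1602))
  dd0 <- dd_onset_minute(sch_dd)
  trace <- rate_at(p, sch_dd, dd0:(dd0 + 4 * 1602))
  cyc1 <- which.max(trace[1:1602])
  cyc2 <- which.max(trace[1603:3204]) + 1602
  expect_equal((cyc2 - cyc1) / 60, 26.7, tolerance = 1e-6)
  expect_equal(((cyc2 - cyc1) - 1440) / 60, 2.7, tolerance = 1e-6)
})

test_that("free-run property: rate autocorrelation peaks at lag tau", {
  p <- individual_params(26.7, template = tpl_s)
  dd0 <- dd_onset_minute(sch_dd)
  x <- rate_at(p, sch_dd, dd0:schedule_minutes(sch_dd))
  lags_h <- seq(18, 30, by = 0.1)
  ac <- vapply(lags_h, function(L) {
    k <- round(L * 60)
    stats::cor(x[1:(length(x) - k)], x[(k + 1):length(x)])
  }, numeric(1))
  expect_equal(lags_h[which.max(ac)], 26.7)
})

test_that("simulated counts are reproducible Poisson draws around rate_at", {
  p <- individual_params(25, template = tpl_s, seed = 77)
  r1 <- simulate_individual(p, sch_dd)
  r2 <- simulate_individual(p, sch_dd)
  expect_identical(r1$counts, r2$counts)
  # zero-amplitude template -> all-zero record
  z <- waveform_template(0, 5, 13, baseline_rate = 0, peak_rate = 1e-12)
  pz <- individual_params(24, template = z, seed = 1)
  expect_true(all(simulate_individual(pz, sch_dd)$counts == 0))
  # Poisson CLT at a fixed minute over 200 seeded replicates
  t0 <- 300L  # ZT 4.98, near peak
  lam <- rate_at(p, sch_dd, t0)
  draws <- vapply(1:200, function(s) {
    ps <- individual_params(25, template = tpl_s, seed = s)
    simulate_individual(ps, sch_dd)$counts[t0]
  }, numeric(1))
  expect_lt(abs(mean(draws) - lam), 3 * sqrt(lam / 200))
})

test_that("cohort draws follow the requested parameters and line nesting", {
  tpl <- tpl_s
  sp1 <- cohort_spec(1, tau_mean = 24.5, tau_sd = 0, between_line_sd = 0,
                     template = tpl, schedule = sch_dd)
  expect_equal(simulate_cohort(sp1)$truth$tau_true, 24.5)
  # 64 individuals -> 2 monitor files of 32 channels
  sp64 <- cohort_spec(64, template = tpl, schedule = sch_dd, master_seed = 3)
  out <- withr::local_tempdir()
  files <- simulate_cohort(sp64, out_dir = out)$files
  expect_length(files$dam, 2)
  map <- read.csv(files$channel_map)
  expect_equal(nrow(map), 64)
  expect_equal(max(map$channel), 32)
  # sampling theory: truth mean near tau_mean at large n
  sp <- cohort_spec(500, tau_mean = 25, tau_sd = 0.5, between_line_sd = 0,
                    n_lines = 10, template = tpl, schedule = sch_dd,
                    master_seed = 9)
  expect_lt(abs(mean(simulate_cohort(sp)$truth$tau_true) - 25),
            3 * 0.5 / sqrt(500))
  # individuals of one line share the line-level intercept
  spl <- cohort_spec(40, tau_sd = 0, between_line_sd = 0.5, n_lines = 4,
                     template = tpl, schedule = sch_dd, master_seed = 2)
  tr <- simulate_cohort(spl)$truth
  expect_equal(max(tapply(tr$tau_true, tr$line, function(v)
    max(v) - min(v))), 0)
  expect_error(cohort_spec(0, template = tpl, schedule = sch_dd), "at least 1")
})

test_that("cohort output is byte-identical from the same master seed", {
  pr <- cohort_presets(master_seed = 5)
  spec <- pr$south_LD08
  spec$n <- 3L
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(spec, out_dir = d1)
  simulate_cohort(spec, out_dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("presets plant the published population parameters", {
  pr <- cohort_presets()
  expect_equal(pr$south_isogenic$tau_mean, 24.3)
  expect_equal(pr$north_isogenic$tau_mean, 26.7)
  expect_equal(pr$COR_virgin_F$tau_mean, 24.6)
  expect_equal(pr$OUL_virgin_F$tau_mean, 25.42)
  expect_equal(pr$south_LD16$template$peak_zt, 5)
  expect_equal(pr$north_LD16$template$peak_zt, 8)
  expect_equal(pr$south_LD16$template$onset_zt, 0)
  expect_equal(pr$north_LD16$template$offset_zt, 16)
  expect_equal(pr$south_LD08$template$onset_zt, 21.5)
  expect_equal(pr$north_LD08$template$offset_zt, 10.5)
  expect_equal(pr$south_LD08$schedule$segments$light_hours[1], 8)
})
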
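#' @title Parametric activity waveforms
#'
#' @description
#' The generator drives per-minute Poisson beam-cross counts with a smooth
#' unimodal daily waveform parameterised directly by the three phase markers
#' it should plant: activity rises from `baseline_rate` at `onset_zt` to
#' `peak_rate` at `peak_zt` along a raised-cosine ramp, falls back to
#' baseline at `offset_zt` along a second raised-cosine ramp, and stays at
#' baseline outside the (circular) active window. All phases are in hours of
#' internal phase (equal to ZT under entrainment) and wrap mod 24.
#'
#' @param onset_zt,peak_zt,offset_zt marker phases in hours, `[0, 24)`;
#'   onset -> peak -> offset must be circularly ordered within one cycle
#' @param baseline_rate,peak_rate expected beam crosses per minute at the
#'   nocturnal baseline and at the activity peak
#' @return an object of class `waveform_template`
#' @export
waveform_template <- function(onset_zt, peak_zt, offset_zt,
                              baseline_rate = 0.1, peak_rate = 8) {
  up <- (peak_zt - onset_zt) %% 24
  down <- (offset_zt - peak_zt) %% 24
  if (up <= 0 || down <= 0 || up + down >= 24)
    stop("onset, peak, offset must be circularly ordered within one cycle")
  if (peak_rate <= baseline_rate)
    stop("peak_rate must exceed baseline_rate")
  if (baseline_rate < 0) stop("baseline_rate must be non-negative")
  structure(list(onset_zt = onset_zt %% 24, peak_zt = peak_zt %% 24,
                 offset_zt = offset_zt %% 24, baseline_rate = baseline_rate,
                 peak_rate = peak_rate, up = up, down = down),
            class = "waveform_template")
}

#' Waveform rate at a given internal phase
#'
#' @param template a [waveform_template()]
#' @param phi internal phase in hours (vectorised)
#' @return expected counts/min at each phase
#' @export
template_rate <- function(template, phi) {
  amp <- template$peak_rate - template$baseline_rate
  d <- (phi - template$onset_zt) %% 24
  r <- rep(template$baseline_rate, length(d))
  rising <- d < template$up
  falling <- !rising & d < template$up + template$down
  r[rising] <- template$baseline_rate +
    amp * (1 - cos(pi * d[rising] / template$up)) / 2
  r[falling] <- template$baseline_rate +
    amp * (1 + cos(pi * (d[falling] - template$up) / template$down)) / 2
  r
}

#' Time-averaged rate of a waveform over one cycle
#'
#' The raised-cosine ramps average to the midpoint of baseline and peak, so
#' the 24-h mean is `baseline + (peak - baseline)/2 * active_hours/24`.
#' Arrhythmic individuals emit this constant rate.
#'
#' @param template a [waveform_template()]
#' @export
template_mean_rate <- function(template) {
  amp <- template$peak_rate - template$baseline_rate
  template$baseline_rate + amp / 2 * (template$up + template$down) / 24
}

#' Per-individual simulation parameters
#'
#' @param tau_h free-running period in hours; must lie in `[18, 30]` for
#'   rhythmic individuals (the periodogram search range)
#' @param rhythmic logical; arrhythmic individuals emit a constant rate
#'   equal to the time-average of their template
#' @param template a [waveform_template()]
#' @param death_minute optional minute after which counts are zero
#' @param seed integer RNG seed for this individual
#' @export
individual_params <- function(tau_h = 24, rhythmic = TRUE, template,
                              death_minute = NA_integer_, seed = 1L) {
  if (rhythmic && (tau_h < 18 || tau_h > 30))
    stop("tau_h must lie in [18, 30] for rhythmic individuals")
  structure(list(tau_h = tau_h, rhythmic = rhythmic, template = template,
                 death_minute = death_minute, seed = as.integer(seed)),
            class = "individual_params")
}

#' Expected beam-cross rate of an individual over a schedule
#'
#' Under LD segments the internal phase equals ZT (perfect entrainment, no
#' masking). At the LD-to-DD transition the phase is continuous, and under
#' DD it advances by `24 / tau_h` hours of subjective time per real hour, so
#' the expected rate free-runs with period `tau_h`.
#'
#' @param params an [individual_params()]
#' @param schedule a [light_schedule()]
#' @param t minute index or vector thereof
#' @return expected counts/min at each minute
#' @export
rate_at <- function(params, schedule, t) {
  if (any(t < 1 | t > schedule_minutes(schedule)))
    stop("t outside the schedule")
  if (!params$rhythmic)
    return(rep(template_mean_rate(params$template), length(t)))
  phi <- zt_at(schedule, t)
  dd0 <- dd_onset_minute(schedule)
  if (!is.na(dd0)) {
    dd <- t >= dd0
    phi[dd] <- (zt_at(schedule, dd0) +
                  (t[dd] - dd0) / 60 * 24 / params$tau_h) %% 24
  }
  template_rate(params$template, phi)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulate one individual's activity record
#'
#' Counts are drawn per minute from a Poisson law with mean [rate_at()];
#' minutes after `death_minute` are zero. Reproducible from `params$seed`.
#'
#' @param params an [individual_params()]
#' @param schedule a [light_schedule()]
#' @param individual_id id for the resulting record
#' @param meta metadata list passed to [activity_record()]
#' @return an [activity_record()]
#' @export
simulate_individual <- function(params, schedule, individual_id = "ind1",
                                meta = list()) {
  n <- schedule_minutes(schedule)
  lambda <- rate_at(params, schedule, seq_len(n))
  counts <- with_seed(params$seed, stats::rpois(n, lambda))
  if (!is.na(params$death_minute) && params$death_minute < n)
    counts[(params$death_minute + 1L):n] <- 0L
  activity_record(individual_id, counts, schedule, meta = meta)
}

#' Cohort simulation specification
#'
#' Individual free-running periods are drawn as
#' `tau = tau_mean + u_line + e`, with a line-level intercept
#' `u_line ~ N(0, between_line_sd^2)` shared within isofemale line and
#' `e ~ N(0, tau_sd^2)`, truncated to `[18, 30]` h. Rhythmic flags are
#' Bernoulli(`prop_rhythmic`); a fraction `prop_dead` of individuals die at
#' a uniform time within the middle of the recording.
#'
#' @param n number of individuals
#' @param tau_mean,tau_sd mean and within-line SD of tau, hours
#' @param prop_rhythmic fraction of rhythmic individuals
#' @param template a [waveform_template()]
#' @param schedule a [light_schedule()]
#' @param population population code (e.g. "OUL", "COR")
#' @param latitude degrees north
#' @param sex "F" or "M"
#' @param mating "virgin" or "mated"
#' @param n_lines number of isofemale lines
#' @param between_line_sd SD of the line-level tau intercept, hours
#' @param prop_dead fraction of individuals that die mid-recording
#' @param master_seed integer master seed
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(n, tau_mean = 24, tau_sd = 0.25, prop_rhythmic = 1,
                        template, schedule, population = "POP",
                        latitude = 50, sex = "F", mating = "virgin",
                        n_lines = 5, between_line_sd = 0.1, prop_dead = 0,
                        master_seed = 1L) {
  if (n < 1) stop("n must be at least 1")
  if (prop_rhythmic < 0 || prop_rhythmic > 1)
    stop("prop_rhythmic must be in [0, 1]")
  if (tau_sd < 0 || between_line_sd < 0) stop("SDs must be non-negative")
  structure(list(n = as.integer(n), tau_mean = tau_mean, tau_sd = tau_sd,
                 prop_rhythmic = prop_rhythmic, template = template,
                 schedule = schedule, population = population,
                 latitude = latitude, sex = sex, mating = mating,
                 n_lines = as.integer(n_lines),
                 between_line_sd = between_line_sd, prop_dead = prop_dead,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Simulate a cohort
#'
#' Draws per-individual parameters from a [cohort_spec()], simulates every
#' record, and returns the records together with the ground-truth table
#' used by planted-parameter recovery tests. If `out_dir` is given, the
#' cohort is also written out as DAM2 monitor files (32 individuals per
#' monitor), a channel-map CSV and a truth-table CSV, so the whole pipeline
#' can be exercised through the same file reader as real data.
#'
#' @param spec a [cohort_spec()]
#' @param out_dir optional directory for DAM2 + CSV output
#' @return list with `records` (list of [activity_record()]), `truth`
#'   (data.frame: individual_id, line, population, latitude, sex, mating,
#'   tau_true, rhythmic, death_minute), and, when written, `files`
#' @export
simulate_cohort <- function(spec, out_dir = NULL) {
  n <- spec$n
  draws <- with_seed(spec$master_seed, {
    line_idx <- rep_len(seq_len(spec$n_lines), n)
    u_line <- stats::rnorm(spec$n_lines, 0, spec$between_line_sd)
    tau <- spec$tau_mean + u_line[line_idx] + stats::rnorm(n, 0, spec$tau_sd)
    tau <- pmin(pmax(tau, 18), 30)
    rhythmic <- stats::runif(n) < spec$prop_rhythmic
    total_min <- schedule_minutes(spec$schedule)
    dies <- stats::runif(n) < spec$prop_dead
    death <- ifelse(dies,
                    floor(stats::runif(n, 0.15 * total_min, 0.85 * total_min)),
                    NA_integer_)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    list(line_idx = line_idx, tau = tau, rhythmic = rhythmic,
         death = death, seeds = seeds)
  })
  ids <- sprintf("%s_%03d", spec$population, seq_len(n))
  lines <- sprintf("%s_L%02d", spec$population, draws$line_idx)
  meta_common <- list(population = spec$population, latitude = spec$latitude,
                      sex = spec$sex, mating = spec$mating)
  records <- lapply(seq_len(n), function(i) {
    p <- individual_params(tau_h = draws$tau[i],
                           rhythmic = draws$rhythmic[i],
                           template = spec$template,
                           death_minute = draws$death[i],
                           seed = draws$seeds[i])
    simulate_individual(p, spec$schedule, individual_id = ids[i],
                        meta = c(meta_common, list(line = lines[i])))
  })
  names(records) <- ids
  truth <- data.frame(individual_id = ids, line = lines,
                      population = spec$population, latitude = spec$latitude,
                      sex = spec$sex, mating = spec$mating,
                      tau_true = draws$tau, rhythmic = draws$rhythmic,
                      death_minute = draws$death,
                      stringsAsFactors = FALSE)
  out <- list(records = records, truth = truth, spec = spec)
  if (!is.null(out_dir)) out$files <- write_cohort(out, out_dir)
  out
}

#' Write a simulated cohort as DAM2 files plus CSV metadata
#'
#' @param cohort result of [simulate_cohort()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list of written paths
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort$spec
  n <- length(cohort$records)
  n_monitors <- ceiling(n / 32)
  start <- as.POSIXct(paste("2019-06-01", spec$schedule$zt0_clock_time),
                      tz = "UTC")
  ts <- start + 60 * (seq_len(schedule_minutes(spec$schedule)) - 1)
  light <- light_state_at(spec$schedule, seq_len(schedule_minutes(spec$schedule)))
  dam_paths <- character(n_monitors)
  map <- NULL
  for (m in seq_len(n_monitors)) {
    idx <- ((m - 1) * 32 + 1):min(m * 32, n)
    counts <- matrix(0L, schedule_minutes(spec$schedule), 32L)
    for (j in seq_along(idx))
      counts[, j] <- cohort$records[[idx[j]]]$counts
    mon_id <- sprintf("%s_M%02d", spec$population, m)
    mon <- dam_monitor(mon_id, ts, counts, light = light)
    dam_paths[m] <- file.path(out_dir, paste0(mon_id, ".txt"))
    write_dam2(mon, dam_paths[m])
    map <- rbind(map, data.frame(
      individual_id = cohort$truth$individual_id[idx],
      monitor = mon_id, channel = seq_along(idx),
      population = spec$population, latitude = spec$latitude,
      line = cohort$truth$line[idx], sex = spec$sex, mating = spec$mating,
      stringsAsFactors = FALSE))
  }
  map_path <- file.path(out_dir, "channel_map.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(map, map_path, row.names = FALSE)
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE)
  invisible(list(dam = dam_paths, channel_map = map_path,
                 truth = truth_path))
}

.population_latitudes <- c(OUL = 65.06, TUR = 61.26, LAT = 56.86,
                           HAM = 53.61, SCH = 50.33, SWI = 46.74,
                           COR = 42.38)

#' Built-in cohort presets
#'
#' Named [cohort_spec()]s whose planted parameters are the published
#' population values for *Nasonia vitripennis*: free-running periods of
#' 24.3 h (southern isogenic lines), 26.7 h (northern isogenic lines),
#' 24.6 h (Corsica virgin females) and 25.42 h (Oulu virgin females), and
#' the long-day / short-day activity templates (LD16:08 south onset ZT 0,
#' peak ZT 5, offset ZT 13; north 2/8/16; LD08:16 south 21.5/2.5/8; north
#' 0/4/10.5). Free-run presets use the standard protocol of 4 days LD16:8
#' entrainment followed by 10 days DD; profile presets use 10 days of the
#' stated LD cycle.
#'
#' @param baseline_rate,peak_rate beam-cross rates (counts/min) handed to
#'   every template
#' @param tau_sd within-line SD of tau (h)
#' @param between_line_sd between-line SD of tau (h)
#' @param master_seed master seed stored in each preset
#' @return named list of [cohort_spec()]s
#' @export
cohort_presets <- function(baseline_rate = 0.1, peak_rate = 8,
                           tau_sd = 0.25, between_line_sd = 0.1,
                           master_seed = 1L) {
  tpl <- function(on, pk, off)
    waveform_template(on, pk, off, baseline_rate, peak_rate)
  south16 <- tpl(0, 5, 13); north16 <- tpl(2, 8, 16)
  south08 <- tpl(21.5, 2.5, 8); north08 <- tpl(0, 4, 10.5)
  dd <- ld_dd_schedule(16, 8, ld_days = 4, dd_days = 10)
  ld16 <- ld_schedule(16, 8, n_days = 10)
  ld08 <- ld_schedule(8, 16, n_days = 10)
  mk <- function(tau, template, schedule, population, n = 30)
    cohort_spec(n = n, tau_mean = tau, tau_sd = tau_sd, prop_rhythmic = 1,
                template = template, schedule = schedule,
                population = population,
                latitude = unname(.population_latitudes[population]),
                sex = "F", mating = "virgin", n_lines = 5,
                between_line_sd = between_line_sd,
                master_seed = master_seed)
  list(
    south_isogenic = mk(24.3,  south16, dd, "COR"),
    north_isogenic = mk(26.7,  north16, dd, "OUL"),
    COR_virgin_F   = mk(24.6,  south16, dd, "COR"),
    OUL_virgin_F   = mk(25.42, north16, dd, "OUL"),
    south_LD16 = mk(24, south16, ld16, "COR", n = 25),
    north_LD16 = mk(24, north16, ld16, "OUL", n = 25),
    south_LD08 = mk(24, south08, ld08, "COR", n = 25),
    north_LD08 = mk(24, north08, ld08, "OUL", n = 25)
  )
}
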
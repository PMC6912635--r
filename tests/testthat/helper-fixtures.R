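# fixture builders shared across test files

# random valid monitor with n 1-min readings
make_monitor <- function(n = 60, seed = 1, monitor_id = "M1") {
  set.seed(seed)
  ts <- as.POSIXct("2019-06-01 08:00:00", tz = "UTC") + 60 * (seq_len(n) - 1)
  counts <- matrix(rpois(n * 32, 2), n, 32)
  dam_monitor(monitor_id, ts, counts,
              light = as.integer((seq_len(n) %% 120) < 60))
}

# record built from an explicit per-minute count vector
make_record <- function(counts, schedule = NULL, id = "w1") {
  if (is.null(schedule))
    schedule <- ld_schedule(16, 8, n_days = length(counts) / 1440)
  activity_record(id, counts, schedule, meta = list(population = "COR"))
}

# deterministic unimodal day: `high` counts/min inside [on, off) ZT, else 0
square_day <- function(on, off, high = 5, base = 0) {
  zt <- (seq_len(1440) - 1) / 60
  inside <- if (on <= off) zt >= on & zt < off else zt >= on | zt < off
  ifelse(inside, high, base)
}
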
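#' Circular statistics on the 24-hour clock
#'
#' Phase markers are circular quantities: times 23.5 h and 0.5 h average to
#' 0.0, not 12.0. `circ_mean` is the direction of the resultant vector,
#' `circ_sd` the circular standard deviation `sqrt(-2 log Rbar)` rescaled to
#' hours, and `circ_diff` the signed difference wrapped to
#' `(-period/2, period/2]`.
#'
#' @param x numeric vector of phases (hours)
#' @param period wrap period, default 24 h
#' @param na.rm drop missing values
#' @return hours
#' @export
circ_mean <- function(x, period = 24, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  a <- x * 2 * pi / period
  m <- (atan2(mean(sin(a)), mean(cos(a))) * period / (2 * pi)) %% period
  if (period - m < 1e-9) m <- 0   # canonicalise phases a hair below the wrap
  m
}

#' @rdname circ_mean
#' @export
circ_sd <- function(x, period = 24, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  a <- x * 2 * pi / period
  r <- sqrt(mean(sin(a))^2 + mean(cos(a))^2)
  if (r <= 0) return(Inf)
  sqrt(-2 * log(r)) * period / (2 * pi)
}

#' @rdname circ_mean
#' @param a,b phases in hours
#' @export
circ_diff <- function(a, b, period = 24) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

# circular index sequence of length n starting at `from`
.circ_order <- function(n, from) ((from - 1L + seq_len(n) - 1L) %% n) + 1L

.night_window_default <- function(schedule) {
  md <- dark_phase(schedule)$mid_dark_zt
  c((md - 2) %% 24, (md + 2) %% 24)
}

.zt_in_window <- function(zt, window) {
  lo <- window[1]; hi <- window[2]
  if (lo <= hi) zt >= lo & zt < hi else zt >= lo | zt < hi
}

#' Average daily activity profile
#'
#' Folds LD recordings on Zeitgeber time and averages, first across days
#' within an individual and then across individuals, expressing activity as
#' average beam crosses per minute per ZT bin. The first `skip_days`
#' entrainment days are excluded (default 4), and only days an individual
#' completed alive enter its average.
#'
#' @param records list of [activity_record()]s sharing one LD schedule
#' @param skip_days initial days to exclude
#' @param bin_minutes ZT bin width; must divide 1440
#' @param quiet_hours terminal-silence threshold for [mark_dead()]
#' @return object of class `daily_profile` with `zt` (bin centres, h),
#'   `activity` (crosses/min), `n_days`, `n_individuals`, `bin_minutes`
#' @export
daily_profile <- function(records, skip_days = 4, bin_minutes = 20,
                          quiet_hours = 24) {
  if (1440 %% bin_minutes != 0) stop("bin_minutes must divide 1440")
  sched <- records[[1]]$schedule
  for (r in records)
    if (!schedules_identical(r$schedule, sched))
      stop("records with mixed light schedules cannot be pooled")
  n_days_total <- schedule_days(sched)
  if (skip_days >= n_days_total)
    stop("no days remain after skipping ", skip_days, " entrainment days")
  nb <- 1440L %/% bin_minutes
  per_ind <- lapply(records, function(rec) {
    rec <- mark_dead(rec, quiet_hours = quiet_hours)
    days <- (skip_days + 1):n_days_total
    days <- days[days * 1440 <= rec$alive_until]
    if (length(days) == 0L) return(NULL)
    day_bins <- vapply(days, function(d) {
      v <- rec$counts[((d - 1) * 1440 + 1):(d * 1440)]
      colSums(matrix(v, nrow = bin_minutes))
    }, numeric(nb))
    rowMeans(day_bins) / bin_minutes
  })
  used <- !vapply(per_ind, is.null, logical(1))
  if (!any(used)) stop("no individual contributed a usable day")
  prof <- rowMeans(do.call(cbind, per_ind[used]))
  structure(list(zt = (seq_len(nb) - 0.5) * bin_minutes / 60,
                 activity = prof, n_days = n_days_total - skip_days,
                 n_individuals = sum(used),
                 bin_minutes = as.integer(bin_minutes), schedule = sched),
            class = "daily_profile")
}

#' @export
print.daily_profile <- function(x, ...) {
  cat("Daily activity profile: ", length(x$zt), " ZT bins of ",
      x$bin_minutes, " min, ", x$n_individuals, " individuals x ",
      x$n_days, " days; mean ", round(mean(x$activity), 3),
      " crosses/min\n", sep = "")
  invisible(x)
}

#' Plot a daily activity profile
#'
#' Bar-style profile over ZT with the scheduled dark phase shaded.
#'
#' @param x a [daily_profile()]
#' @param ... passed to [graphics::plot()]
#' @export
plot.daily_profile <- function(x, ...) {
  graphics::plot(x$zt, x$activity, type = "h", lwd = 3, lend = 1,
                 xlab = "Zeitgeber time (h)", ylab = "Beam crosses / min",
                 xlim = c(0, 24), ...)
  dp <- dark_phase(x$schedule)
  graphics::rect(dp$lights_off_zt, graphics::par("usr")[3], 24,
                 graphics::par("usr")[4],
                 col = grDevices::grey(0.2, alpha = 0.15), border = NA)
  invisible(x)
}

#' Detect the daily activity onset
#'
#' Operationalises "the first time activity starts to rise consecutively":
#' with baseline mean `b` and SD `s` over the night-reference window, the
#' onset is the start of the first bin, scanning circularly from mid-dark,
#' whose value exceeds `b + threshold_sd * s` and whose following bin is
#' not lower. Returns `NA` when no bin qualifies (e.g. an all-zero day).
#'
#' @param bins one day of 20-min (or other) binned counts aligned to ZT 0
#' @param bin_minutes bin width of `bins`
#' @param schedule the [light_schedule()] (supplies mid-dark and the
#'   default night window)
#' @param night_ref ZT window `c(start, end)` for the baseline; default is
#'   the 4-h window centred on mid-dark, which stays quiescent even for
#'   phenotypes with anticipatory activity before lights-on
#' @param threshold_sd baseline SD multiplier (default 2)
#' @return onset in ZT hours, or `NA`
#' @export
detect_onset <- function(bins, bin_minutes, schedule, night_ref = NULL,
                         threshold_sd = 2) {
  nb <- length(bins)
  if (nb * bin_minutes != 1440) stop("bins must cover exactly one day")
  if (is.null(night_ref)) night_ref <- .night_window_default(schedule)
  starts <- (seq_len(nb) - 1) * bin_minutes / 60
  ref <- .zt_in_window(starts, night_ref)
  if (sum(ref) < 2) stop("night reference window covers fewer than 2 bins")
  thr <- mean(bins[ref]) + threshold_sd * stats::sd(bins[ref])
  origin <- floor(dark_phase(schedule)$mid_dark_zt * 60 / bin_minutes) + 1L
  ord <- .circ_order(nb, origin)
  for (i in ord) {
    nxt <- if (i == nb) 1L else i + 1L
    if (bins[i] > thr && bins[nxt] >= bins[i]) return(starts[i])
  }
  NA_real_
}

#' Detect the daily activity offset
#'
#' The offset is when activity returns to the level stable during the
#' night: the start of the first bin after the day's peak (scanning
#' circularly) whose value is at or below `b + threshold_sd * s` for two
#' consecutive bins.
#'
#' @inheritParams detect_onset
#' @return offset in ZT hours, or `NA`
#' @export
detect_offset <- function(bins, bin_minutes, schedule, night_ref = NULL,
                          threshold_sd = 2) {
  nb <- length(bins)
  if (nb * bin_minutes != 1440) stop("bins must cover exactly one day")
  if (is.null(night_ref)) night_ref <- .night_window_default(schedule)
  starts <- (seq_len(nb) - 1) * bin_minutes / 60
  ref <- .zt_in_window(starts, night_ref)
  if (sum(ref) < 2) stop("night reference window covers fewer than 2 bins")
  thr <- mean(bins[ref]) + threshold_sd * stats::sd(bins[ref])
  if (all(bins <= thr)) return(NA_real_)   # flat day: no peak to descend from
  origin <- floor(dark_phase(schedule)$mid_dark_zt * 60 / bin_minutes) + 1L
  ord <- .circ_order(nb, origin)
  peak_pos <- ord[which.max(bins[ord])]
  after <- .circ_order(nb, peak_pos)[-1]
  for (i in after) {
    nxt <- if (i == nb) 1L else i + 1L
    if (bins[i] <= thr && bins[nxt] <= thr) return(starts[i])
  }
  NA_real_
}

#' Detect the daily activity peak
#'
#' Smooths one day of minute-resolution counts with a centred circular
#' moving average (default 30 min), suppressing isolated spikes, and
#' returns the ZT of the global maximum of the smoothed track. Smoothing
#' turns an isolated spike into a flat-topped plateau, so exact ties are
#' resolved as the circular centre of the maximal plateau encountered
#' earliest in a circular scan from mid-dark (a single spike at ZT 5 is
#' reported as 5.0; of two equal spikes, the one nearer the scan origin
#' wins). An all-zero (or constant) day has no defined peak and is `NA`.
#'
#' @param minutes one day (1440 values) of per-minute counts
#' @param schedule the [light_schedule()] (supplies the scan origin)
#' @param smooth_minutes moving-average width
#' @return peak in ZT hours, or `NA`
#' @export
detect_peak <- function(minutes, schedule, smooth_minutes = 30) {
  if (length(minutes) != 1440L) stop("minutes must cover exactly one day")
  if (all(minutes == 0)) return(NA_real_)
  sm <- as.numeric(stats::filter(minutes,
                                 rep(1 / smooth_minutes, smooth_minutes),
                                 sides = 2, circular = TRUE))
  n <- 1440L
  maxv <- max(sm)
  is_max <- sm >= maxv - 1e-9 * max(1, abs(maxv))
  if (all(is_max)) return(NA_real_)
  origin <- floor(dark_phase(schedule)$mid_dark_zt * 60) + 1L
  ord <- .circ_order(n, origin)
  start <- NA_integer_
  for (i in ord) {
    prev <- if (i == 1L) n else i - 1L
    if (is_max[i] && !is_max[prev]) { start <- i; break }
  }
  len <- 1L
  j <- start
  repeat {
    j <- if (j == n) 1L else j + 1L
    if (!is_max[j] || j == start) break
    len <- len + 1L
  }
  # minute i covers [i-1, i) min; the plateau midpoint is its marker
  (((start - 1L) + len / 2) / 60) %% 24
}

#' Per-day phase markers for a cohort
#'
#' Computes onset, peak and offset for every analysed day of every
#' individual: onset/offset on 20-min binned tracks and the peak on the
#' 30-min-smoothed minute track, all per the defaults of [detect_onset()],
#' [detect_offset()] and [detect_peak()]. The first `skip_days` entrainment
#' days and any days after death are excluded.
#'
#' @param records list of [activity_record()]s sharing one LD schedule
#' @param skip_days initial days to exclude (default 4)
#' @param bin_minutes bin width for onset/offset tracks (default 20)
#' @param smooth_minutes smoothing window for the peak track (default 30)
#' @param night_ref baseline ZT window; see [detect_onset()]
#' @param threshold_sd baseline SD multiplier
#' @param quiet_hours terminal-silence threshold for [mark_dead()]
#' @return data.frame: individual_id, day, onset, peak, offset (ZT hours,
#'   `NA` where undefined)
#' @export
marker_table <- function(records, skip_days = 4, bin_minutes = 20,
                         smooth_minutes = 30, night_ref = NULL,
                         threshold_sd = 2, quiet_hours = 24) {
  sched <- records[[1]]$schedule
  for (r in records)
    if (!schedules_identical(r$schedule, sched))
      stop("records with mixed light schedules cannot be pooled")
  n_days_total <- schedule_days(sched)
  rows <- lapply(records, function(rec) {
    rec <- mark_dead(rec, quiet_hours = quiet_hours)
    days <- (skip_days + 1):n_days_total
    days <- days[days * 1440 <= rec$alive_until]
    if (length(days) == 0L) return(NULL)
    do.call(rbind, lapply(days, function(d) {
      v <- rec$counts[((d - 1) * 1440 + 1):(d * 1440)]
      b20 <- colSums(matrix(v, nrow = bin_minutes))
      data.frame(individual_id = rec$individual_id, day = d,
                 onset = detect_onset(b20, bin_minutes, sched, night_ref,
                                      threshold_sd),
                 peak = detect_peak(v, sched, smooth_minutes),
                 offset = detect_offset(b20, bin_minutes, sched, night_ref,
                                        threshold_sd),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Summarise phase markers
#'
#' Circular mean and circular SD per marker. By default, per-day markers
#' are first averaged (circularly) within individual, and the group mean is
#' taken over individuals; the pooled per-day summary is also reported.
#'
#' @param markers data.frame from [marker_table()]
#' @return object of class `phase_markers`: `mean` and `sd` (named vectors
#'   over onset/peak/offset, group level), `per_individual` (data.frame of
#'   per-individual circular means), `per_day_mean`/`per_day_sd` (pooled
#'   across all days), `n_individuals`, `n_days`
#' @export
summarize_markers <- function(markers) {
  mk <- c("onset", "peak", "offset")
  if (all(is.na(unlist(markers[mk]))))
    stop("all markers are missing")
  per_ind <- do.call(rbind, lapply(split(markers, markers$individual_id),
    function(d) data.frame(individual_id = d$individual_id[1],
                           onset = circ_mean(d$onset),
                           peak = circ_mean(d$peak),
                           offset = circ_mean(d$offset),
                           n_days = nrow(d), stringsAsFactors = FALSE)))
  rownames(per_ind) <- NULL
  structure(list(
    mean = vapply(mk, function(m) circ_mean(per_ind[[m]]), numeric(1)),
    sd = vapply(mk, function(m) circ_sd(per_ind[[m]]), numeric(1)),
    per_individual = per_ind,
    per_day_mean = vapply(mk, function(m) circ_mean(markers[[m]]), numeric(1)),
    per_day_sd = vapply(mk, function(m) circ_sd(markers[[m]]), numeric(1)),
    n_individuals = nrow(per_ind), n_days = nrow(markers)),
    class = "phase_markers")
}

#' @export
print.phase_markers <- function(x, ...) {
  cat("Phase markers (", x$n_individuals, " individuals, ", x$n_days,
      " individual-days):\n", sep = "")
  for (m in names(x$mean))
    cat(sprintf("  %-6s ZT %5.2f h (circular SD %.2f h)\n", m,
                x$mean[m], x$sd[m]))
  invisible(x)
}
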
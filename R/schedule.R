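#' Light schedules
#'
#' A light schedule is an ordered sequence of segments, each either a
#' light--dark cycle (`"LD"`, with `light_hours + dark_hours == 24`) or
#' constant darkness (`"DD"`), repeated for a whole number of days.
#' Recording is assumed to start at the first lights-on instant, which
#' defines Zeitgeber time zero (ZT 0). Under DD, ZT continues by 24-h
#' extrapolation of the last LD segment, so ZT at minute `m` is simply the
#' elapsed time modulo 24 h.
#'
#' @param segments data.frame with columns `regime` ("LD" or "DD"),
#'   `light_hours`, `dark_hours`, `n_days`.
#' @param zt0_clock_time clock time of lights-on, "HH:MM:SS"; used only when
#'   stamping DAM2 files with calendar timestamps.
#' @return an object of class `light_schedule`
#' @export
light_schedule <- function(segments, zt0_clock_time = "08:00:00") {
  stopifnot(is.data.frame(segments),
            all(c("regime", "light_hours", "dark_hours", "n_days") %in%
                  names(segments)))
  if (nrow(segments) == 0L) stop("schedule must contain at least one segment")
  if (!all(segments$regime %in% c("LD", "DD")))
    stop("segment regime must be 'LD' or 'DD'")
  ld <- segments$regime == "LD"
  if (any(ld & (segments$light_hours + segments$dark_hours != 24)))
    stop("LD segments must have light_hours + dark_hours == 24")
  if (any(segments$n_days < 1 | segments$n_days != round(segments$n_days)))
    stop("n_days must be positive integers")
  structure(list(segments = segments, zt0_clock_time = zt0_clock_time),
            class = "light_schedule")
}

#' @rdname light_schedule
#' @param ld_days days of LD entrainment before release into darkness
#' @param dd_days days of constant darkness
#' @param light_hours,dark_hours hours of light and dark per 24-h LD cycle
#' @export
ld_dd_schedule <- function(light_hours = 16, dark_hours = 8, ld_days = 4,
                           dd_days = 10, zt0_clock_time = "08:00:00") {
  light_schedule(data.frame(
    regime = c("LD", "DD"),
    light_hours = c(light_hours, 0),
    dark_hours = c(dark_hours, 24),
    n_days = c(ld_days, dd_days)), zt0_clock_time)
}

#' @rdname light_schedule
#' @param n_days number of LD days
#' @export
ld_schedule <- function(light_hours = 16, dark_hours = 8, n_days = 10,
                        zt0_clock_time = "08:00:00") {
  light_schedule(data.frame(regime = "LD", light_hours = light_hours,
                            dark_hours = dark_hours, n_days = n_days),
                 zt0_clock_time)
}

#' @export
print.light_schedule <- function(x, ...) {
  cat("Light schedule (", schedule_days(x), " days, ZT0 at ",
      x$zt0_clock_time, "):\n", sep = "")
  for (i in seq_len(nrow(x$segments))) {
    s <- x$segments[i, ]
    if (s$regime == "LD")
      cat(sprintf("  LD %02d:%02d x %d days\n", s$light_hours, s$dark_hours,
                  s$n_days))
    else
      cat(sprintf("  DD x %d days\n", s$n_days))
  }
  invisible(x)
}

#' @rdname light_schedule
#' @param schedule a `light_schedule`
#' @export
schedule_days <- function(schedule) sum(schedule$segments$n_days)

#' @rdname light_schedule
#' @export
schedule_minutes <- function(schedule) schedule_days(schedule) * 1440L

#' Zeitgeber time of recording minutes
#'
#' Minute `m` (1-based) covers the interval starting `(m - 1)` minutes after
#' lights-on of day 1; its ZT is the elapsed time at the start of that
#' interval, modulo 24 h. The same extrapolated scale applies under DD.
#'
#' @param schedule a `light_schedule`
#' @param minute 1-based minute index or vector thereof
#' @return ZT in hours, in `[0, 24)`
#' @export
zt_at <- function(schedule, minute) ((minute - 1) / 60) %% 24

#' Light state at recording minutes
#'
#' @inheritParams zt_at
#' @return integer vector, 1 where the light is on, 0 otherwise
#' @export
light_state_at <- function(schedule, minute) {
  seg <- schedule$segments
  seg_end_day <- cumsum(seg$n_days)
  day <- (minute - 1) %/% 1440 + 1
  idx <- findInterval(day - 1, c(0, seg_end_day), rightmost.closed = FALSE)
  idx[day > seg_end_day[length(seg_end_day)]] <- NA_integer_
  zt <- zt_at(schedule, minute)
  out <- integer(length(minute))
  isld <- seg$regime[idx] == "LD"
  out[isld] <- as.integer(zt[isld] < seg$light_hours[idx[isld]])
  out
}

#' First minute of constant darkness
#'
#' @param schedule a `light_schedule`
#' @return 1-based minute index of the first DD minute, or `NA` if the
#'   schedule has no DD segment
#' @export
dd_onset_minute <- function(schedule) {
  seg <- schedule$segments
  i <- which(seg$regime == "DD")[1]
  if (is.na(i)) return(NA_integer_)
  as.integer(sum(seg$n_days[seq_len(i - 1)]) * 1440 + 1)
}

#' Dark-phase geometry of the entraining LD cycle
#'
#' Returns the ZT of lights-off, the mid-dark point and the dark-phase length
#' of the last (or only) LD segment; used as defaults for phase-marker
#' detection windows.
#'
#' @param schedule a `light_schedule`
#' @return list with `lights_off_zt`, `mid_dark_zt`, `dark_hours`
#' @export
dark_phase <- function(schedule) {
  seg <- schedule$segments
  i <- which(seg$regime == "LD")
  if (length(i) == 0L) stop("schedule has no LD segment")
  i <- i[length(i)]
  off <- seg$light_hours[i]
  list(lights_off_zt = off,
       mid_dark_zt = (off + seg$dark_hours[i] / 2) %% 24,
       dark_hours = seg$dark_hours[i])
}

schedules_identical <- function(a, b) {
  isTRUE(all.equal(a$segments, b$segments, check.attributes = FALSE))
}
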
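#' @title TriKinetics DAM2 monitor files
#'
#' @description
#' A DAM2 monitor records, once per minute, how many times each of 32
#' individuals interrupted an infrared beam. The on-disk format is
#' tab-delimited with 10 metadata columns (reading index, date `"dd mmm yy"`,
#' time `"HH:MM:SS"`, status code, five device fields, light-sensor flag)
#' followed by 32 count columns. `dam_monitor` is the in-memory form:
#' validated monotone 1-minute timestamps plus an n x 32 count matrix.
#'
#' @param monitor_id character label for the monitor
#' @param timestamps `POSIXct` vector, strictly increasing at 1-min spacing
#' @param counts integer matrix with 32 columns of non-negative counts
#' @param status integer status codes per row (1 = OK)
#' @param light integer 0/1 light-sensor readings per row
#' @param imputed logical per row; `TRUE` marks rows inserted by gap filling
#' @return an object of class `dam_monitor`
#' @export
dam_monitor <- function(monitor_id, timestamps, counts,
                        status = rep(1L, nrow(counts)),
                        light = rep(0L, nrow(counts)),
                        imputed = rep(FALSE, nrow(counts))) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0L && ncol(counts) != 32L)
    stop("a DAM2 monitor must have exactly 32 count channels")
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(timestamps) != nrow(counts))
    stop("timestamps and counts disagree in length")
  if (nrow(counts) > 1L) {
    d <- as.numeric(diff(timestamps), units = "mins")
    if (any(d != 1))
      stop("timestamps must be strictly increasing at 1-minute spacing")
  }
  structure(list(monitor_id = monitor_id, timestamps = timestamps,
                 status = as.integer(status), light = as.integer(light),
                 counts = counts, imputed = imputed),
            class = "dam_monitor")
}

#' @export
print.dam_monitor <- function(x, ...) {
  cat("DAM2 monitor '", x$monitor_id, "': ", nrow(x$counts),
      " 1-min readings x 32 channels", sep = "")
  if (nrow(x$counts) > 0L)
    cat(", ", format(x$timestamps[1]), " .. ",
        format(x$timestamps[nrow(x$counts)]), sep = "")
  cat("\n")
  if (any(x$status != 1L))
    cat("  ", sum(x$status != 1L), " rows with non-OK status\n", sep = "")
  if (any(x$imputed))
    cat("  ", sum(x$imputed), " gap-filled (imputed) rows\n", sep = "")
  invisible(x)
}

.dam_months <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                 "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

# locale-independent "dd mmm yy" + "HH:MM:SS" -> POSIXct (UTC)
.parse_dam_timestamp <- function(date_str, time_str) {
  parts <- matrix(unlist(strsplit(date_str, " ", fixed = TRUE)),
                  ncol = 3, byrow = TRUE)
  mon <- match(parts[, 2], .dam_months)
  if (anyNA(mon)) stop("unrecognised month abbreviation in DAM2 date field")
  yy <- as.integer(parts[, 3])
  year <- ifelse(yy < 70, 2000L + yy, 1900L + yy)
  as.POSIXct(sprintf("%04d-%02d-%02d %s", year, mon,
                     as.integer(parts[, 1]), time_str), tz = "UTC")
}

.format_dam_timestamp <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  list(date = sprintf("%02d %s %02d", lt$mday, .dam_months[lt$mon + 1L],
                      lt$year %% 100L),
       time = sprintf("%02d:%02d:%02d", lt$hour, lt$min, floor(lt$sec)))
}

#' Read a DAM2 monitor file
#'
#' Parses the tab-delimited TriKinetics DAM2 layout and validates the
#' timestamp sequence. Rows whose status code is not the OK value are kept
#' and flagged via the `status` field, never silently dropped. Timestamp
#' gaps or duplicates are an error by default; with `fill_gaps = TRUE`,
#' missing minutes are inserted as zero-count rows flagged as imputed.
#'
#' @param path path to a DAM2 text file
#' @param monitor_id label for the monitor; defaults to the file name
#' @param fill_gaps insert zero-count rows for missing minutes instead of
#'   failing
#' @param ok_status integer status code meaning a valid reading (default 1)
#' @return a [dam_monitor()]
#' @export
read_dam2 <- function(path, monitor_id = basename(path), fill_gaps = FALSE,
                      ok_status = 1L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(dam_monitor(monitor_id, as.POSIXct(character(), tz = "UTC"),
                       matrix(integer(), 0, 32)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 42L))
    stop(sprintf("malformed DAM2 row at line %d of '%s': %d fields, expected 42",
                 which(nf != 42L)[1], path, nf[which(nf != 42L)[1]]))
  m <- matrix(unlist(fields), ncol = 42L, byrow = TRUE)
  ts <- .parse_dam_timestamp(m[, 2], m[, 3])
  status <- as.integer(m[, 4])
  light <- as.integer(m[, 10])
  counts <- matrix(as.integer(m[, 11:42]), ncol = 32L)
  if (anyNA(counts))
    stop(sprintf("non-numeric count field in '%s'", path))
  imputed <- rep(FALSE, length(ts))
  if (length(ts) > 1L) {
    d <- as.numeric(diff(ts), units = "mins")
    if (any(d <= 0))
      stop(sprintf("duplicate or non-increasing timestamp in '%s' at rows: %s",
                   path, paste(which(d <= 0) + 1L, collapse = ", ")))
    if (any(d > 1)) {
      if (!fill_gaps)
        stop(sprintf("time gap in '%s' after rows: %s (use fill_gaps = TRUE to impute zeros)",
                     path, paste(which(d > 1), collapse = ", ")))
      full <- seq(ts[1], ts[length(ts)], by = "1 min")
      idx <- match(as.numeric(full), as.numeric(ts))
      newc <- matrix(0L, length(full), 32L)
      newc[!is.na(idx), ] <- counts[idx[!is.na(idx)], ]
      status <- ifelse(is.na(idx), ok_status, status[idx])
      light <- ifelse(is.na(idx), 0L, light[idx])
      imputed <- is.na(idx)
      ts <- full
      counts <- newc
    }
  }
  mon <- dam_monitor(monitor_id, ts, counts, status, light, imputed)
  if (any(mon$status != ok_status))
    message(sum(mon$status != ok_status), " rows in '", path,
            "' have non-OK status and are flagged")
  mon
}

#' Write a DAM2 monitor file
#'
#' Writes the standard tab-delimited DAM2 layout; the payload (timestamps,
#' status, light sensor, all 32 count columns) round-trips bit-exactly
#' through [read_dam2()]. The five device fields are written as zeros.
#'
#' @param monitor a [dam_monitor()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dam2 <- function(monitor, path) {
  n <- nrow(monitor$counts)
  if (n == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  f <- .format_dam_timestamp(monitor$timestamps)
  meta <- cbind(seq_len(n), f$date, f$time, monitor$status,
                0L, 0L, 0L, 0L, 0L, monitor$light)
  lines <- do.call(paste, c(split(meta, col(meta)),
                            split(monitor$counts, col(monitor$counts)),
                            sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Per-individual activity records
#'
#' An `activity_record` holds one individual's minute-resolution beam-cross
#' counts, the light schedule it experienced, its metadata, and
#' `alive_until`, the last minute index treated as alive (set by
#' [mark_dead()]; defaults to the full series).
#'
#' @param individual_id character id
#' @param counts integer vector of per-minute counts
#' @param schedule the [light_schedule()] of the recording
#' @param meta named list (population, latitude, line, sex, mating, ...)
#' @param alive_until last minute index considered alive
#' @return an object of class `activity_record`
#' @export
activity_record <- function(individual_id, counts, schedule,
                            meta = list(), alive_until = length(counts)) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(counts) != schedule_minutes(schedule))
    stop("counts length must equal the schedule duration in minutes")
  if (alive_until > length(counts)) stop("alive_until exceeds series length")
  structure(list(individual_id = individual_id, counts = counts,
                 schedule = schedule, meta = meta,
                 alive_until = as.integer(alive_until)),
            class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  cat("Activity record '", x$individual_id, "': ", length(x$counts),
      " min (", length(x$counts) / 1440, " days), ", sum(x$counts),
      " beam crosses", sep = "")
  if (x$alive_until < length(x$counts))
    cat("; flagged dead after minute ", x$alive_until, sep = "")
  cat("\n")
  invisible(x)
}

#' Attach channel metadata to a monitor
#'
#' Splits a 32-channel monitor into one [activity_record()] per mapped
#' channel. Unmapped channels are ignored with a notice; a channel index
#' outside 1..32 or a duplicated individual id is an error.
#'
#' @param monitor a [dam_monitor()]
#' @param channel_map data.frame with columns `individual_id`, `channel`,
#'   and any metadata columns (e.g. `population`, `latitude`, `line`, `sex`,
#'   `mating`)
#' @param schedule the [light_schedule()] of the recording
#' @return named list of [activity_record()]s
#' @export
attach_metadata <- function(monitor, channel_map, schedule) {
  stopifnot(is.data.frame(channel_map),
            all(c("individual_id", "channel") %in% names(channel_map)))
  ch <- channel_map$channel
  if (any(ch < 1 | ch > 32 | ch != round(ch)))
    stop("channel indices must be integers in 1..32")
  if (anyDuplicated(channel_map$individual_id))
    stop("duplicate individual_id in channel map")
  if (anyDuplicated(ch)) stop("duplicate channel in channel map")
  n_unmapped <- 32L - length(ch)
  if (n_unmapped > 0L)
    message(n_unmapped, " unmapped channels on monitor '",
            monitor$monitor_id, "' ignored")
  if (nrow(monitor$counts) != schedule_minutes(schedule))
    stop("monitor length does not match the schedule duration")
  meta_cols <- setdiff(names(channel_map), c("individual_id", "channel"))
  recs <- lapply(seq_along(ch), function(i) {
    activity_record(channel_map$individual_id[i], monitor$counts[, ch[i]],
                    schedule, meta = as.list(channel_map[i, meta_cols,
                                                         drop = FALSE]))
  })
  names(recs) <- channel_map$individual_id
  recs
}

#' Flag dead animals by terminal inactivity
#'
#' The original screening for dead animals was visual inspection of
#' actograms; this automated surrogate flags an individual as dead at the
#' start of a terminal all-zero run of at least `quiet_hours`. Idempotent,
#' and never extends `alive_until`.
#'
#' @param record an [activity_record()]
#' @param quiet_hours minimum terminal silence, in hours, to call death
#' @return the record with `alive_until` updated
#' @export
mark_dead <- function(record, quiet_hours = 24) {
  x <- record$counts[seq_len(record$alive_until)]
  n <- length(x)
  if (n == 0L) return(record)
  nz <- which(x > 0)
  last_active <- if (length(nz)) nz[length(nz)] else 0L
  run <- n - last_active
  if (run >= quiet_hours * 60)
    record$alive_until <- as.integer(last_active)
  record
}

#' Is a record usable for analysis?
#'
#' A record flagged dead before completing `min_days` full days of the
#' analysed segment is excluded entirely.
#'
#' @param record an [activity_record()]
#' @param min_days minimum complete days alive
#' @param from first minute of the analysed segment (default 1)
#' @export
is_alive_enough <- function(record, min_days = 2, from = 1L) {
  record$alive_until - from + 1L >= min_days * 1440
}

#' Binned activity series
#'
#' Sums per-minute counts into fixed-width bins aligned to ZT 0 (bins start
#' at lights-on, the start of the record). A trailing partial bin is
#' dropped; the sum over whole bins equals the sum of the raw counts they
#' cover.
#'
#' @param x an [activity_record()] or an integer vector of per-minute counts
#' @param bin_minutes bin width in minutes; must divide 1440
#' @param use_alive for records, truncate at `alive_until` first
#' @return an object of class `binned_series` with fields `values`,
#'   `bin_minutes`, `start_minute`
#' @export
bin_counts <- function(x, bin_minutes, use_alive = TRUE) {
  if (1440 %% bin_minutes != 0)
    stop("bin_minutes must divide 1440")
  if (inherits(x, "activity_record")) {
    v <- if (use_alive) x$counts[seq_len(x$alive_until)] else x$counts
  } else v <- as.integer(x)
  nb <- length(v) %/% bin_minutes
  vals <- if (nb > 0L)
    colSums(matrix(v[seq_len(nb * bin_minutes)], nrow = bin_minutes))
  else numeric(0)
  structure(list(values = as.numeric(vals),
                 bin_minutes = as.integer(bin_minutes), start_minute = 1L),
            class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  cat("Binned series: ", length(x$values), " bins of ", x$bin_minutes,
      " min (total ", sum(x$values), " counts)\n", sep = "")
  invisible(x)
}
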
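test_that("a hand-written DAM2 file parses into timestamps and 32 channels", {
  path <- withr::local_tempfile(fileext = ".txt")
  rows <- sapply(0:2, function(i)
    paste(c(i + 1, "01 Jun 19", sprintf("08:%02d:00", i), 1,
            0, 0, 0, 0, 0, 1, 0:31), collapse = "\t"))
  writeLines(rows, path)
  mon <- read_dam2(path)
  expect_equal(nrow(mon$counts), 3)
  expect_equal(ncol(mon$counts), 32)
  expect_equal(mon$counts[1, ], 0:31)
  expect_equal(as.numeric(diff(mon$timestamps), units = "mins"), c(1, 1))
  expect_equal(mon$light, rep(1L, 3))
})

test_that("write/read round trip is the identity on the payload", {
  for (seed in 1:5) {
    mon <- make_monitor(n = 50, seed = seed)
    path <- withr::local_tempfile(fileext = ".txt")
    write_dam2(mon, path)
    back <- read_dam2(path, monitor_id = mon$monitor_id)
    expect_identical(back$counts, mon$counts)
    expect_equal(back$timestamps, mon$timestamps)
    expect_identical(back$status, mon$status)
    expect_identical(back$light, mon$light)
  }
  # empty monitor round-trips to an empty file
  empty <- dam_monitor("E", as.POSIXct(character(), tz = "UTC"),
                       matrix(integer(), 0, 32))
  path <- withr::local_tempfile(fileext = ".txt")
  write_dam2(empty, path)
  expect_equal(nrow(read_dam2(path)$counts), 0)
})

test_that("a single row with constant counts serialises as 32 trailing 7s", {
  mon <- dam_monitor("M7", as.POSIXct("2019-06-01 08:00:00", tz = "UTC"),
                     matrix(7L, 1, 32))
  path <- withr::local_tempfile(fileext = ".txt")
  write_dam2(mon, path)
  fields <- strsplit(readLines(path), "\t")[[1]]
  expect_length(fields, 42)
  expect_equal(fields[11:42], rep("7", 32))
  expect_equal(fields[2:3], c("01 Jun 19", "08:00:00"))
})

test_that("malformed rows and timestamp problems fail loudly with locations", {
  path <- withr::local_tempfile(fileext = ".txt")
  mon <- make_monitor(n = 10)
  write_dam2(mon, path)
  lines <- readLines(path)
  writeLines(c(lines[1], "broken\trow"), path)
  expect_error(read_dam2(path), "line 2")
  # a dropped middle row is a gap: error by default, imputed on request
  writeLines(lines[-5], path)
  expect_error(read_dam2(path), "gap")
  filled <- read_dam2(path, fill_gaps = TRUE)
  expect_equal(nrow(filled$counts), 10)
  expect_true(filled$imputed[5])
  expect_equal(unname(filled$counts[5, ]), rep(0L, 32))
  expect_identical(filled$counts[-5, ], mon$counts[-5, ])
})

test_that("attach_metadata maps channels to records and validates the map", {
  sch <- ld_schedule(16, 8, n_days = 1)
  mon <- make_monitor(n = 1440)
  map2 <- data.frame(individual_id = c("a", "b"), channel = c(3, 17),
                     population = "COR", sex = "F")
  recs <- suppressMessages(attach_metadata(mon, map2, sch))
  expect_length(recs, 2)
  expect_equal(recs[["a"]]$counts, unname(mon$counts[, 3]))
  expect_equal(recs[["b"]]$meta$population, "COR")

  expect_error(attach_metadata(mon, data.frame(individual_id = "x",
                                               channel = 33), sch), "1..32")
  expect_error(attach_metadata(mon, data.frame(individual_id = c("x", "x"),
                                               channel = c(1, 2)), sch),
               "duplicate")
  full <- data.frame(individual_id = sprintf("w%02d", 1:32), channel = 1:32)
  expect_length(attach_metadata(mon, full, sch), 32)
})

test_that("mark_dead flags terminal silence, is idempotent and monotone", {
  sch <- ld_schedule(16, 8, n_days = 3)
  x <- rep(1L, 3 * 1440)
  x[(3 * 1440 - 30 * 60 + 1):(3 * 1440)] <- 0L     # dead for the last 30 h
  r <- mark_dead(make_record(x, sch))
  expect_equal(r$alive_until, 3 * 1440 - 30 * 60)
  expect_equal(mark_dead(r)$alive_until, r$alive_until)  # idempotent

  y <- rep(1L, 3 * 1440)
  y[2000:(2000 + 12 * 60)] <- 0L                    # mid-series lull only
  expect_equal(mark_dead(make_record(y, sch))$alive_until, 3 * 1440)
})

test_that("planted deaths in a simulated cohort are exactly the flagged ones", {
  pr <- cohort_presets(master_seed = 7)
  spec <- pr$south_isogenic
  spec$n <- 40L
  spec$prop_dead <- 0.1
  co <- simulate_cohort(spec)
  flagged <- vapply(co$records, function(r) {
    r <- mark_dead(r)
    r$alive_until < length(r$counts)
  }, logical(1))
  expect_identical(unname(flagged), !is.na(co$truth$death_minute))
  for (i in which(!is.na(co$truth$death_minute)))
    expect_lte(mark_dead(co$records[[i]])$alive_until,
               co$truth$death_minute[i])
})

test_that("bin_counts sums aligned bins and conserves totals", {
  sch <- ld_schedule(16, 8, n_days = 1)
  b <- bin_counts(rep(1L, 60), 20)
  expect_equal(b$values, c(20, 20, 20))
  r3 <- make_record(rep(2L, 3 * 1440), ld_schedule(16, 8, n_days = 3))
  expect_equal(bin_counts(r3, 1440)$values, rep(2880, 3))
  expect_error(bin_counts(rep(1L, 60), 7), "divide")
  set.seed(42)
  for (bw in c(5, 10, 20, 60, 240)) {
    x <- rpois(1447, 3)                              # partial trailing bin
    b <- bin_counts(x, bw)
    nb <- length(x) %/% bw
    expect_equal(sum(b$values), sum(x[seq_len(nb * bw)]))
  }
})
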
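# Epoch processing: hour restriction, non-wear runs, valid days, spectrum.

test_that("non-wear detection follows the 60-min zero-run rule exactly", {
  pad <- rep(30, 60)  # 10 min of nonzero epochs
  below <- make_stream(list(c(pad, rep(0, 359), pad)))   # 59.83 min of zeros
  at <- make_stream(list(c(pad, rep(0, 360), pad)))      # 60.00 min of zeros
  expect_true(all(detect_non_wear(below)))
  w <- detect_non_wear(at)
  expect_equal(sum(!w), 360)
  expect_true(all(w[1:60]) && all(w[(60 + 361):length(w)]))

  none <- constant_subject(1, cpm = 300)
  expect_true(all(detect_non_wear(none)))

  # idempotent and invariant to flanking wear epochs
  w2 <- detect_non_wear(make_stream(list(c(rep(30, 6), rep(0, 360), pad))))
  expect_equal(sum(!w2), 360)

  bad <- make_stream(list(rep(10, 100)), epoch_length = 7)
  expect_error(detect_non_wear(bad), "divide 60")
})

test_that("non-wear runs are evaluated within days, not across them", {
  # 30 min of zeros at each day's end/start: 60 min total but split by the
  # overnight gap, so neither run reaches the window
  d1 <- c(full_day(300, 420), rep(0, 180))
  d2 <- c(rep(0, 180), full_day(300, 420))
  st <- make_stream(list(d1, d2))
  expect_true(all(detect_non_wear(st)))
})

test_that("hour restriction keeps 06:00:00-23:59:59 inclusive", {
  t0 <- as.POSIXct("2015-03-02 05:59:50", tz = "UTC")
  ts <- t0 + seq(0, by = 10, length.out = 4)  # 05:59:50 06:00:00 06:00:10 ...
  st <- epoch_stream("x", ts, c(1, 2, 3, 4))
  r <- restrict_hours(st)
  expect_equal(r$counts, c(2, 3, 4))
  expect_equal(format(r$timestamps[1], "%H:%M:%S", tz = "UTC"), "06:00:00")

  late <- epoch_stream("x", as.POSIXct("2015-03-02 23:59:50", tz = "UTC"), 5)
  expect_equal(n_epochs_public(restrict_hours(late)), 1L)
  mid <- epoch_stream("x", as.POSIXct("2015-03-03 00:00:00", tz = "UTC"), 5)
  expect_equal(n_epochs_public(restrict_hours(mid)), 0L)

  empty <- restrict_hours(epoch_stream("x", ts[0], numeric(0)))
  expect_equal(n_epochs_public(empty), 0L)
})

test_that("day validity uses the 480-min and 4-day thresholds exactly", {
  d480 <- full_day(300, 480)
  d479 <- full_day(300, 479)
  st <- make_stream(list(d480, d479))
  days <- validate_days(st, detect_non_wear(st))
  expect_equal(days$valid, c(TRUE, FALSE))
  expect_equal(days$wear_minutes, c(480, 479))
  expect_false(attr(days, "subject_valid"))

  st3 <- make_stream(replicate(3, d480, simplify = FALSE))
  expect_false(attr(validate_days(st3, detect_non_wear(st3)), "subject_valid"))
  st7 <- make_stream(replicate(7, d480, simplify = FALSE))
  days7 <- validate_days(st7, detect_non_wear(st7))
  expect_equal(sum(days7$valid), 7)
  expect_true(attr(days7, "subject_valid"))
})

test_that("spectrum extraction bins epochs on the cpm scale", {
  # all-zero wear day would be non-wear; use a wear day of 0-99 cpm epochs
  st <- constant_subject(1, cpm = 0)
  w <- rep(TRUE, 2880)  # treat as worn: constructed wear mask
  days <- validate_days(st, w)
  sp <- extract_spectrum(st, w, days)
  expect_length(sp$minutes_per_day, 16)
  expect_equal(unname(sp$minutes_per_day[1]), 480)
  expect_equal(unname(sum(sp$minutes_per_day[-1])), 0)

  # one 10-s epoch with 500 counts -> 3000 cpm -> bin "3000-3499" gets 1/6 min
  day <- full_day(300, 480)
  day[100] <- 500
  st2 <- make_stream(list(day))
  w2 <- detect_non_wear(st2)
  sp2 <- extract_spectrum(st2, w2, validate_days(st2, w2))
  expect_equal(unname(sp2$minutes_per_day["3000-3499"]), 1 / 6)
  expect_equal(unname(sp2$minutes_per_day["250-499"]), 480 - 1 / 6)

  # no valid days signals not-analyzable
  short <- make_stream(list(full_day(300, 100)))
  ws <- detect_non_wear(short)
  expect_error(extract_spectrum(short, ws, validate_days(short, ws)),
               "no valid days")
})

test_that("bin minutes always sum to wear minutes (partition property)", {
  set.seed(9)
  for (i in 1:5) {
    day <- sample(0:2000, 2880, replace = TRUE)
    st <- make_stream(list(day, day + 1))
    w <- detect_non_wear(st)
    days <- validate_days(st, w)
    sp <- extract_spectrum(st, w, days)
    expect_equal(sum(sp$minutes_per_day), sp$mean_wear_minutes)
    expect_equal(sp$mean_wear_minutes, mean(days$wear_minutes[days$valid]))
  }
})

test_that("Evenson summary applies its cut points with inclusive lower edges", {
  st <- constant_subject(2, cpm = 2296)  # exactly on the MPA lower edge
  w <- detect_non_wear(st)
  ev <- evenson_summary(st, w, validate_days(st, w))
  expect_equal(ev$mpa, 480)
  expect_equal(ev$sed + ev$lpa + ev$vpa, 0)
  expect_equal(ev$mvpa, ev$mpa + ev$vpa)
  expect_true(ev$meets_guideline)

  st2 <- constant_subject(2, cpm = 50)
  w2 <- detect_non_wear(st2)  # nonzero counts so all wear
  ev2 <- evenson_summary(st2, w2, validate_days(st2, w2))
  expect_equal(ev2$sed, 480)
  expect_false(ev2$meets_guideline)  # 0 MVPA

  # guideline boundary: 59 min 54 s of MVPA is below, 60 min is at threshold
  mk <- function(n_mvpa) {
    day <- c(rep(3000 / 6, n_mvpa), rep(8, 2880 - n_mvpa))  # rest at 48 cpm
    st <- make_stream(list(day))
    w <- detect_non_wear(st)
    evenson_summary(st, w, validate_days(st, w))
  }
  expect_false(mk(359)$meets_guideline)   # 59.83 min/day MVPA
  expect_true(mk(360)$meets_guideline)    # 60.00 min/day
})

test_that("Evenson classes equal sums of refining fine bins", {
  set.seed(11)
  day <- sample(0:9000, 2880, replace = TRUE)
  st <- make_stream(list(day))
  w <- detect_non_wear(st)
  days <- validate_days(st, w)
  sp <- extract_spectrum(st, w, days)
  ev <- evenson_summary(st, w, days)
  expect_equal(ev$sed, unname(sp$minutes_per_day[1]))  # 0-99 matches SED
})

test_that("60-s epochs reproduce the 10-s spectrum on minute-constant data", {
  set.seed(13)
  minute_cpm <- sample(c(0, 40, 600, 3000, 5000), 480 * 2, replace = TRUE)
  st10 <- make_stream(list(rep(minute_cpm[1:480] / 6, each = 6),
                           rep(minute_cpm[481:960] / 6, each = 6)),
                      epoch_length = 10)
  st60 <- make_stream(list(minute_cpm[1:480], minute_cpm[481:960]),
                      epoch_length = 60)
  get_spec <- function(st) {
    w <- detect_non_wear(st)
    extract_spectrum(st, w, validate_days(st, w))$minutes_per_day
  }
  expect_equal(get_spec(st10), get_spec(st60))
})

test_that("epoch CSV reader and spectrum writer round-trip", {
  st <- list(a = constant_subject(2, cpm = 300, subject_id = "a"),
             b = constant_subject(2, cpm = 2400, subject_id = "b"))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_epoch_csv(st, csv)
  back <- read_epoch_csv(csv)
  expect_named(back, c("a", "b"))
  expect_equal(back$a$counts, st$a$counts)
  expect_equal(as.numeric(back$a$timestamps), as.numeric(st$a$timestamps))

  processed <- lapply(back, process_stream)
  expect_false(processed$a$valid)  # only 2 days
  sm_csv <- withr::local_tempfile(fileext = ".csv")
  st7 <- list(a = constant_subject(7, cpm = 300, subject_id = "a"))
  sp <- process_stream(st7$a)$spectrum
  df <- write_spectrum_csv(list(sp), sm_csv)
  re <- utils::read.csv(sm_csv, check.names = FALSE)
  expect_equal(re$`250-499`, 480)
  expect_equal(re$n_valid_days, 7)
})

test_that("process_stream flags invalid subjects without error", {
  st <- make_stream(list(full_day(300, 100)))
  res <- process_stream(st)
  expect_false(res$valid)
  expect_null(res$spectrum)
})
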
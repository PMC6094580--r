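# Epoch-level accelerometer processing: hour restriction, non-wear detection,
# valid-day filtering, and intensity-spectrum feature extraction.

#' Construct an epoch-level count stream
#'
#' An `epoch_stream` holds the raw accelerometer record for one subject:
#' activity counts summed over fixed-length epochs, with one timestamp per
#' epoch start. Timestamps must be strictly increasing; gaps are allowed
#' (e.g. after hour restriction) but spacing within contiguous stretches must
#' be a multiple of the epoch length.
#'
#' @param subject_id Identifier for the subject (coerced to character).
#' @param timestamps `POSIXct` vector of epoch start times.
#' @param counts Non-negative integer activity counts, one per epoch.
#' @param epoch_length Epoch duration in seconds (default 10).
#' @return An object of class `epoch_stream`.
#' @export
epoch_stream <- function(subject_id, timestamps, counts, epoch_length = 10L) {
  if (!inherits(timestamps, "POSIXct"))
    stop("`timestamps` must be POSIXct")
  if (length(timestamps) != length(counts))
    stop("`timestamps` and `counts` must have the same length")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("`counts` must be finite and non-negative")
  if (length(timestamps) > 1L) {
    d <- diff(as.numeric(timestamps))
    if (any(d <= 0)) stop("`timestamps` must be strictly increasing")
    if (any(abs(d %% epoch_length) > 1e-6 &
            abs(d %% epoch_length - epoch_length) > 1e-6))
      stop("timestamp spacing must be a multiple of `epoch_length`")
  }
  structure(
    list(subject_id = as.character(subject_id)[1],
         timestamps = timestamps,
         counts = as.numeric(counts),
         epoch_length = as.numeric(epoch_length)),
    class = "epoch_stream")
}

#' @export
print.epoch_stream <- function(x, ...) {
  cat(sprintf("<epoch_stream> subject %s: %d epochs of %gs, %d day(s)\n",
              x$subject_id, length(x$counts), x$epoch_length,
              length(unique(stream_dates(x)))))
  invisible(x)
}

n_epochs <- function(stream) length(stream$counts)

# integer days since epoch: cheap grouping key (no Date/character coercion)
stream_daynum <- function(stream)
  as.integer(as.numeric(stream$timestamps) %/% 86400)

stream_dates <- function(stream)
  as.Date(stream_daynum(stream), origin = "1970-01-01")

seconds_of_day <- function(timestamps) as.numeric(timestamps) %% 86400

#' Wear-time and day-validity criteria
#'
#' Defaults follow the standard pediatric protocol: activity restricted to
#' 06:00-23:59, non-wear defined as >= 60 consecutive minutes of zero counts,
#' and a valid measurement requiring >= 8 h of wear per day on >= 4 days.
#'
#' @param min_hours_per_day Minimum wear hours for a day to be valid.
#' @param min_days Minimum number of valid days for a subject to be analyzable.
#' @param nonwear_window_minutes Minimum run length (minutes) of consecutive
#'   zero-count epochs classified as non-wear.
#' @param day_start Start of the daily analysis window, "HH:MM".
#' @param day_end End of the daily analysis window, "HH:MM"; epochs starting
#'   anywhere within that minute are retained.
#' @return An object of class `wear_criteria`.
#' @export
wear_criteria <- function(min_hours_per_day = 8, min_days = 4,
                          nonwear_window_minutes = 60,
                          day_start = "06:00", day_end = "23:59") {
  parse_hm <- function(x) {
    p <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
    p[1] * 3600 + p[2] * 60
  }
  stopifnot(min_hours_per_day > 0, min_days > 0, nonwear_window_minutes > 0)
  structure(
    list(min_hours_per_day = min_hours_per_day,
         min_days = min_days,
         nonwear_window_minutes = nonwear_window_minutes,
         day_start_sec = parse_hm(day_start),
         day_end_sec = parse_hm(day_end) + 59),  # inclusive of the end minute
    class = "wear_criteria")
}

#' Restrict a stream to the daily analysis window
#'
#' Keeps only epochs whose start time falls inside the configured window
#' (default 06:00:00-23:59:59); both boundaries inclusive. Applied before
#' non-wear detection so that zero runs are evaluated within the window.
#'
#' @param stream An [epoch_stream()].
#' @param criteria A [wear_criteria()].
#' @return A restricted `epoch_stream` (possibly empty).
#' @export
restrict_hours <- function(stream, criteria = wear_criteria()) {
  sec <- seconds_of_day(stream$timestamps)
  keep <- sec >= criteria$day_start_sec & sec <= criteria$day_end_sec
  stream$timestamps <- stream$timestamps[keep]
  stream$counts <- stream$counts[keep]
  stream
}

#' Detect non-wear epochs
#'
#' Flags maximal runs of consecutive zero-count epochs whose total duration
#' reaches the non-wear window (default 60 min). Runs are strict (no count
#' spikes tolerated) and are evaluated within each calendar day, so a run
#' never spans the overnight gap introduced by hour restriction.
#'
#' @param stream An [epoch_stream()], typically already hour-restricted.
#' @param criteria A [wear_criteria()].
#' @return Logical wear mask, one element per epoch; `TRUE` = worn.
#' @export
detect_non_wear <- function(stream, criteria = wear_criteria()) {
  if (60 %% stream$epoch_length != 0)
    stop("epoch_length must divide 60 seconds")
  n <- n_epochs(stream)
  if (n == 0L) return(logical(0))
  min_run <- criteria$nonwear_window_minutes * 60 / stream$epoch_length
  wear <- rep(TRUE, n)
  for (idx in split(seq_len(n), stream_daynum(stream))) {
    r <- rle(stream$counts[idx] == 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run))
      wear[idx[starts[k]:ends[k]]] <- FALSE
  }
  wear
}

#' Tabulate wear time per day and flag valid days
#'
#' A day is valid when its wear time (epochs flagged worn, within the
#' restricted window) reaches `min_hours_per_day`; the subject is analyzable
#' when at least `min_days` days are valid.
#'
#' @param stream An [epoch_stream()] (hour-restricted).
#' @param wear Logical wear mask from [detect_non_wear()].
#' @param criteria A [wear_criteria()].
#' @return A data frame with columns `date`, `wear_minutes`, `valid`, plus
#'   attribute `subject_valid` (logical).
#' @export
validate_days <- function(stream, wear, criteria = wear_criteria()) {
  stopifnot(length(wear) == n_epochs(stream))
  daynum <- stream_daynum(stream)
  per_day <- tapply(wear, daynum, sum)
  wear_min <- as.numeric(per_day) * stream$epoch_length / 60
  out <- data.frame(date = as.Date(as.integer(names(per_day)),
                                   origin = "1970-01-01"),
                    wear_minutes = wear_min,
                    valid = wear_min >= criteria$min_hours_per_day * 60)
  attr(out, "subject_valid") <- sum(out$valid) >= criteria$min_days
  out
}

#' Intensity bin scheme on the counts-per-minute scale
#'
#' Bins are half-open intervals `[edge_i, edge_{i+1})` with the last bin
#' unbounded above. The default 16-interval scheme spans the full intensity
#' spectrum: 0-99, 100-249, 250-499, 500-999, then 500-cpm steps to 4999,
#' 1000-cpm steps to 7999, and >= 8000 cpm.
#'
#' @param edges Strictly increasing lower edges, starting at 0.
#' @return An object of class `bin_scheme` with `edges` and `labels`.
#' @export
bin_scheme <- function(edges = default_bin_edges()) {
  stopifnot(edges[1] == 0, !is.unsorted(edges, strictly = TRUE))
  k <- length(edges)
  labels <- c(paste0(edges[-k], "-", edges[-1] - 1), paste0(">=", edges[k]))
  structure(list(edges = edges, labels = labels), class = "bin_scheme")
}

#' @rdname bin_scheme
#' @export
default_bin_edges <- function() {
  c(0, 100, 250, 500, 1000, 1500, 2000, 2500, 3000,
    3500, 4000, 4500, 5000, 6000, 7000, 8000)
}

# Evenson descriptive cut points (SED / LPA / MPA / VPA lower edges, cpm).
evenson_edges <- function() c(0, 100, 2296, 4012)

bin_assign <- function(cpm, edges) findInterval(cpm, edges)

#' Extract the per-subject intensity spectrum
#'
#' Each wear epoch on a valid day is scaled to counts per minute
#' (`counts * 60 / epoch_length`), assigned to exactly one bin, and epoch
#' counts per bin are converted to minutes. The subject-level value is the
#' unweighted mean over valid days.
#'
#' @param stream An [epoch_stream()] (hour-restricted).
#' @param wear Logical wear mask from [detect_non_wear()].
#' @param days Day table from [validate_days()].
#' @param scheme A [bin_scheme()].
#' @return An `intensity_spectrum`: `minutes_per_day` (one value per bin),
#'   `n_valid_days`, `mean_wear_minutes`, `overall_cpm`, `subject_id`.
#' @export
extract_spectrum <- function(stream, wear, days, scheme = bin_scheme()) {
  valid_days <- as.integer(unclass(days$date[days$valid]))
  if (length(valid_days) == 0L)
    stop("subject has no valid days; not analyzable")
  daynum <- stream_daynum(stream)
  use <- wear & (daynum %in% valid_days)
  cpm <- stream$counts[use] * 60 / stream$epoch_length
  day_f <- factor(daynum[use], levels = valid_days)
  bin_f <- factor(bin_assign(cpm, scheme$edges),
                  levels = seq_along(scheme$labels))
  counts_tab <- table(day_f, bin_f)                      # epochs per day x bin
  mins <- counts_tab * stream$epoch_length / 60
  minutes_per_day <- colMeans(mins)
  names(minutes_per_day) <- scheme$labels
  wear_min_days <- days$wear_minutes[days$valid]
  total_wear_min <- sum(wear_min_days)
  structure(
    list(subject_id = stream$subject_id,
         minutes_per_day = minutes_per_day,
         n_valid_days = length(valid_days),
         mean_wear_minutes = mean(wear_min_days),
         overall_cpm = sum(stream$counts[use]) / total_wear_min),
    class = "intensity_spectrum")
}

#' Descriptive physical-activity summary with Evenson cut points
#'
#' Reports sedentary (0-99 cpm), light (100-2295), moderate (2296-4011),
#' vigorous (>= 4012) and moderate-to-vigorous (>= 2296) minutes per day, and
#' whether the subject meets the guideline of a mean >= 60 min MVPA/day.
#'
#' @inheritParams extract_spectrum
#' @return A data frame with one row: `sed`, `lpa`, `mpa`, `vpa`, `mvpa`
#'   (min/day) and `meets_guideline`.
#' @export
evenson_summary <- function(stream, wear, days) {
  sp <- extract_spectrum(stream, wear, days, bin_scheme(evenson_edges()))
  m <- unname(sp$minutes_per_day)
  data.frame(subject_id = sp$subject_id,
             sed = m[1], lpa = m[2], mpa = m[3], vpa = m[4],
             mvpa = m[3] + m[4],
             meets_guideline = (m[3] + m[4]) >= 60)
}

#' Run the full epoch-to-spectrum chain for one subject
#'
#' Applies, in fixed order: hour restriction, non-wear detection, day
#' validation, then spectrum extraction and the Evenson summary. Subjects
#' failing the validity criteria are reported, not errored.
#'
#' @param stream An [epoch_stream()].
#' @param criteria A [wear_criteria()].
#' @param scheme A [bin_scheme()].
#' @return A list: `valid` (logical), `days`, and when valid also
#'   `spectrum` and `evenson`.
#' @export
process_stream <- function(stream, criteria = wear_criteria(),
                           scheme = bin_scheme()) {
  st <- restrict_hours(stream, criteria)
  wear <- detect_non_wear(st, criteria)
  days <- validate_days(st, wear, criteria)
  valid <- isTRUE(attr(days, "subject_valid"))
  out <- list(subject_id = stream$subject_id, valid = valid, days = days)
  if (valid) {
    out$spectrum <- extract_spectrum(st, wear, days, scheme)
    out$evenson <- evenson_summary(st, wear, days)
  }
  out
}

#' Read epoch-level count data from a long CSV
#'
#' Expects columns `subject_id`, `timestamp` (ISO-8601, interpreted as UTC)
#' and `counts`; one row per epoch.
#'
#' @param path CSV file path.
#' @param epoch_length Epoch duration in seconds.
#' @return Named list of [epoch_stream()] objects, one per subject.
#' @export
read_epoch_csv <- function(path, epoch_length = 10L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "counts")
  if (!all(need %in% names(df)))
    stop("epoch CSV must have columns: ", paste(need, collapse = ", "))
  ts <- as.POSIXct(sub("T", " ", df$timestamp, fixed = TRUE), tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in epoch CSV")
  out <- lapply(split(seq_len(nrow(df)), df$subject_id), function(i) {
    o <- i[order(ts[i])]
    epoch_stream(df$subject_id[o[1]], ts[o], df$counts[o], epoch_length)
  })
  out[order(names(out))]
}

#' Write per-subject intensity spectra to CSV
#'
#' One row per subject: metadata columns followed by one column per bin.
#'
#' @param spectra List of `intensity_spectrum` objects.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_spectrum_csv <- function(spectra, path) {
  rows <- lapply(spectra, function(sp) {
    data.frame(subject_id = sp$subject_id,
               n_valid_days = sp$n_valid_days,
               mean_wear_minutes = sp$mean_wear_minutes,
               overall_cpm = sp$overall_cpm,
               as.list(sp$minutes_per_day),
               check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Assemble the feature matrix from processed subjects
#'
#' @param processed List of results from [process_stream()].
#' @return A list with `X` (subjects x bins matrix of min/day, rownames =
#'   subject ids), `meta` (wear metadata data frame) and `excluded`
#'   (character vector of subject ids failing wear criteria).
#' @export
spectrum_matrix <- function(processed) {
  ok <- vapply(processed, function(p) p$valid, logical(1))
  specs <- lapply(processed[ok], `[[`, "spectrum")
  X <- do.call(rbind, lapply(specs, `[[`, "minutes_per_day"))
  rownames(X) <- vapply(specs, `[[`, character(1), "subject_id")
  meta <- data.frame(
    subject_id = rownames(X),
    n_valid_days = vapply(specs, `[[`, numeric(1), "n_valid_days"),
    mean_wear_minutes = vapply(specs, `[[`, numeric(1), "mean_wear_minutes"),
    overall_cpm = vapply(specs, `[[`, numeric(1), "overall_cpm"))
  list(X = X, meta = meta,
       excluded = vapply(processed[!ok], `[[`, character(1), "subject_id"))
}
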
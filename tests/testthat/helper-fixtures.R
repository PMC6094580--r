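# Fixture builders shared across test files. All data are generated in code.

# Contiguous 10-s epoch stream starting 06:00 UTC; counts_by_day is a list of
# per-day count vectors.
make_stream <- function(counts_by_day, subject_id = "t1", epoch_length = 10,
                        date0 = as.Date("2015-03-02"), start = "06:00:00") {
  ts <- do.call(c, lapply(seq_along(counts_by_day), function(d) {
    t0 <- as.POSIXct(paste(date0 + d - 1, start), tz = "UTC")
    t0 + (seq_along(counts_by_day[[d]]) - 1) * epoch_length
  }))
  epoch_stream(subject_id, ts, unlist(counts_by_day), epoch_length)
}

# A full valid day: 480 min of wear at `cpm`, i.e. 2880 ten-second epochs.
full_day <- function(cpm = 300, minutes = 480, epoch_length = 10) {
  rep(cpm * epoch_length / 60, minutes * 60 / epoch_length)
}

# n full valid days at constant cpm
constant_subject <- function(n_days = 7, cpm = 300, minutes = 480, ...) {
  make_stream(replicate(n_days, full_day(cpm, minutes), simplify = FALSE), ...)
}

# Small deterministic metabolic panel with exact, hand-checkable values.
tiny_panel <- function(n = 8, seed = 42) {
  set.seed(seed)
  data.frame(
    subject_id = paste0("p", seq_len(n)),
    sex = rep(c(0, 1), length.out = n),
    age = round(runif(n, 9.8, 10.6), 2),
    body_mass = round(rnorm(n, 37, 5), 1),
    height = round(rnorm(n, 143, 5), 1),
    waist = round(rnorm(n, 62, 5), 1),
    sbp = round(rnorm(n, 105, 8), 1),
    dbp = round(rnorm(n, 58, 6), 1),
    tc = round(rnorm(n, 4.5, 0.5), 2),
    hdl = round(runif(n, 1.2, 1.9), 2),
    tg = round(runif(n, 0.4, 1.4), 2),
    glucose = round(rnorm(n, 5, 0.3), 2),
    insulin = round(runif(n, 30, 80), 1),
    andersen_distance = round(rnorm(n, 900, 90))
  )
}

# Random regression problem with controllable rank-1 signal share.
rank1_problem <- function(n = 200, p = 16, noise_x = 0.3, r2 = 0.5,
                          seed = 1) {
  set.seed(seed)
  t <- rnorm(n)
  load <- runif(p, 0.5, 1.5)
  X <- outer(t, load) + matrix(rnorm(n * p, sd = noise_x), n, p)
  y <- t + rnorm(n, sd = sqrt(1 / r2 - 1))
  list(X = X, y = y, t = t)
}

# Fast small cohort for pipeline-level tests.
small_cohort <- function(n = 120, seed = 3)
  simulate_cohort(cohort_config(n_subjects = n, seed = seed))

n_epochs_public <- function(stream) length(stream$counts)
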
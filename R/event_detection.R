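#' Event-detection parameters
#'
#' Tuning constants for the three trace-analysis algorithms. The defaults
#' follow the published analysis: a binding event must displace the bead by
#' more than 8 nm and last at least 10 ms (threshold method), or reduce the
#' position variance by at least 50% for 10 ms (variance-drop method).
#' `smooth_ms` is the boxcar smoothing applied before thresholding and
#' `page_threshold`/`page_drift` parameterise the Page cumulative-sum test;
#' all three were calibrated on synthetic motor-free baselines so that false
#' detections are rarer than one per 270 s of record.
#'
#' @param min_disp_nm Displacement threshold, nm (default 8).
#' @param min_dur_ms Duration threshold, ms (default 10).
#' @param var_window_ms Sliding variance window of the variance-drop
#'   detector, ms (default 20; short enough to resolve events a few tens of
#'   ms long, long enough that baseline variance estimates do not dip below
#'   half their expectation).
#' @param var_drop_frac Variance-reduction threshold, fraction of baseline
#'   (default 0.5, must be < 1).
#' @param page_threshold Decision level of the Page cumulative sum on the
#'   log variance ratio (default 30; the largest scanned level still
#'   detecting moderate variance drops reliably while producing no false
#'   event on 540 s of motor-free baseline).
#' @param page_drift Drift (reference) term of the cumulative sum
#'   (default 0.5).
#' @param page_window_ms Variance window of the Page detector, ms
#'   (default 5; the cumulative sum does the noise suppression, so a short
#'   window keeps change-point timing sharp).
#' @param smooth_ms Boxcar smoothing window for the threshold detector, ms
#'   (default 10).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_disp_nm = 8, min_dur_ms = 10,
                             var_window_ms = 20, var_drop_frac = 0.5,
                             page_threshold = 30, page_drift = 0.5,
                             page_window_ms = 5, smooth_ms = 10) {
  if (min_disp_nm <= 0) stop("min_disp_nm must be > 0")
  if (min_dur_ms <= 0) stop("min_dur_ms must be > 0")
  if (var_window_ms <= 0) stop("var_window_ms must be > 0")
  if (var_drop_frac <= 0 || var_drop_frac >= 1)
    stop("var_drop_frac must be in (0, 1)")
  if (page_threshold <= 0) stop("page_threshold must be > 0")
  if (page_window_ms <= 0) stop("page_window_ms must be > 0")
  if (smooth_ms < 0) stop("smooth_ms must be >= 0")
  structure(list(min_disp_nm = min_disp_nm, min_dur_ms = min_dur_ms,
                 var_window_ms = var_window_ms, var_drop_frac = var_drop_frac,
                 page_threshold = page_threshold, page_drift = page_drift,
                 page_window_ms = page_window_ms, smooth_ms = smooth_ms),
            class = "detection_params")
}

# centered rolling mean; edges use shrinking windows
roll_mean <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n == 0) return(x)
  cs <- cumsum(c(0, x))
  h <- w %/% 2
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# centered rolling variance (about the local window mean)
roll_var <- function(x, w) {
  n <- length(x)
  if (n == 0) return(x)
  w <- max(2L, as.integer(w))
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  h <- w %/% 2
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  m <- hi - lo + 1
  mu <- (cs[hi + 1] - cs[lo]) / m
  v <- (cs2[hi + 1] - cs2[lo]) / m - mu^2
  pmax(v, 0) * m / pmax(m - 1, 1)
}

trace_fs <- function(trace) {
  meta <- attr(trace, "meta")
  if (!is.null(meta$sample_hz_actual)) return(meta$sample_hz_actual)
  dt <- diff(trace$t_s)
  if (length(dt) == 0) stop("trace too short")
  if (diff(range(dt)) > 1e-9 * mean(dt))
    stop("trace must be uniformly sampled")
  1 / mean(dt)
}

empty_events <- function() {
  data.frame(t_start_s = numeric(0), duration_ms = numeric(0),
             displacement_nm = numeric(0), peak_force_pN = numeric(0))
}

# turn index runs into the standard event data frame
runs_to_events <- function(flag, trace, fs, min_dur_samples, x_smooth) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_dur_samples
  if (!any(keep)) return(empty_events())
  starts <- starts[keep]
  ends <- ends[keep]
  base_x <- median(trace$x_nm)
  base_f <- median(trace$f_pN)
  ev <- data.frame(
    t_start_s = trace$t_s[starts],
    duration_ms = (ends - starts + 1) / fs * 1000,
    displacement_nm = vapply(seq_along(starts), function(i)
      mean(x_smooth[starts[i]:ends[i]]) - base_x, numeric(1)),
    peak_force_pN = vapply(seq_along(starts), function(i)
      max(trace$f_pN[starts[i]:ends[i]]) - base_f, numeric(1)))
  ev[order(ev$t_start_s), , drop = FALSE]
}

#' Displacement-threshold event detector
#'
#' Scores as binding events the contiguous excursions of the (boxcar
#' smoothed, median-baseline-corrected) bead position that exceed
#' `min_disp_nm` and last at least `min_dur_ms`. Excursions separated by a
#' sub-threshold gap are distinct events.
#'
#' @param trace A `trap_trace` (or any data frame with `t_s`, `x_nm`,
#'   `f_pN`), uniformly sampled.
#' @param dp A [detection_params()] object.
#' @return Data frame with one row per event: `t_start_s`, `duration_ms`,
#'   `displacement_nm` (mean smoothed displacement above baseline),
#'   `peak_force_pN` (peak baseline-corrected trap force).
#' @export
detect_threshold <- function(trace, dp = detection_params()) {
  stopifnot(inherits(dp, "detection_params"))
  fs <- trace_fs(trace)
  w <- max(1L, as.integer(round(dp$smooth_ms / 1000 * fs)))
  xs <- roll_mean(trace$x_nm, w)
  y <- xs - median(xs)
  above <- y > dp$min_disp_nm
  runs_to_events(above, trace, fs,
                 max(1L, as.integer(round(dp$min_dur_ms / 1000 * fs))), xs)
}

#' Variance-drop event detector
#'
#' Computes a sliding-window position variance; samples whose variance falls
#' to `var_drop_frac` of the baseline variance (the median windowed variance
#' of the record), in runs lasting at least `min_dur_ms`, are scored as
#' strong-binding events. Used for records whose events are too small or too
#' brief for displacement thresholding.
#'
#' @inheritParams detect_threshold
#' @return Event data frame as in [detect_threshold()].
#' @export
detect_variance_drop <- function(trace, dp = detection_params()) {
  stopifnot(inherits(dp, "detection_params"))
  fs <- trace_fs(trace)
  w <- max(2L, as.integer(round(dp$var_window_ms / 1000 * fs)))
  if (nrow(trace) < 2 * w)
    stop("trace shorter than twice the variance window")
  rv <- roll_var(trace$x_nm, w)
  base_var <- median(rv)
  if (base_var <= 0) return(empty_events())
  low <- rv <= dp$var_drop_frac * base_var
  runs_to_events(low, trace, fs,
                 max(1L, as.integer(round(dp$min_dur_ms / 1000 * fs))),
                 roll_mean(trace$x_nm, w))
}

#' Page cumulative-sum event detector
#'
#' Two-sided change-point detection on the windowed log variance of the
#' record. A downward cumulative sum accumulates evidence for a variance
#' drop (myosin attachment); when it exceeds `page_threshold` the event
#' onset is taken as the first sample of the current positive excursion of
#' the statistic. An upward cumulative sum started at the alarm detects the
#' variance recovery (detachment) and dates the event end the same way.
#'
#' @inheritParams detect_threshold
#' @return Event data frame as in [detect_threshold()].
#' @export
detect_page <- function(trace, dp = detection_params()) {
  stopifnot(inherits(dp, "detection_params"))
  fs <- trace_fs(trace)
  w <- max(2L, as.integer(round(dp$page_window_ms / 1000 * fs)))
  if (nrow(trace) < 2 * w)
    stop("trace shorter than twice the variance window")
  rv <- roll_var(trace$x_nm, w)
  base_var <- median(rv)
  if (base_var <= 0) return(empty_events())
  s <- log(pmax(rv, base_var * 1e-6) / base_var)
  n <- length(s)
  k <- dp$page_drift
  h <- dp$page_threshold
  starts <- integer(0)
  ends <- integer(0)
  i <- 1L
  mode_attach <- TRUE
  D <- 0
  exc_start <- 1L
  cur_start <- NA_integer_
  s_event <- 0 # log variance ratio of the current event (vs baseline)
  while (i <= n) {
    if (mode_attach) {
      # evidence for a variance drop below baseline
      inc <- -s[i] - k
      Dn <- D + inc
      if (Dn <= 0) {
        D <- 0
        exc_start <- i + 1L
      } else {
        if (D == 0) exc_start <- i
        D <- Dn
        if (D > h) {
          cur_start <- exc_start
          s_event <- median(s[exc_start:i])
          mode_attach <- FALSE
          D <- 0
          exc_start <- i + 1L
        }
      }
    } else {
      # evidence for recovery from the event's variance level
      inc <- s[i] - s_event - k
      Dn <- D + inc
      if (Dn <= 0) {
        D <- 0
        exc_start <- i + 1L
      } else {
        if (D == 0) exc_start <- i
        D <- Dn
        if (D > h) {
          starts <- c(starts, cur_start)
          ends <- c(ends, exc_start)
          mode_attach <- TRUE
          D <- 0
          exc_start <- i + 1L
        }
      }
    }
    i <- i + 1L
  }
  if (!mode_attach && !is.na(cur_start)) {
    starts <- c(starts, cur_start)
    ends <- c(ends, n)
  }
  if (length(starts) == 0) return(empty_events())
  min_dur <- max(1L, as.integer(round(dp$min_dur_ms / 1000 * fs)))
  keep <- (ends - starts + 1) >= min_dur
  starts <- starts[keep]
  ends <- ends[keep]
  if (length(starts) == 0) return(empty_events())
  xs <- roll_mean(trace$x_nm, w)
  base_x <- median(trace$x_nm)
  base_f <- median(trace$f_pN)
  data.frame(
    t_start_s = trace$t_s[starts],
    duration_ms = (ends - starts + 1) / fs * 1000,
    displacement_nm = vapply(seq_along(starts), function(j)
      mean(xs[starts[j]:ends[j]]) - base_x, numeric(1)),
    peak_force_pN = vapply(seq_along(starts), function(j)
      max(trace$f_pN[starts[j]:ends[j]]) - base_f, numeric(1)))
}

#' Summarise detected binding events
#'
#' @param events Event data frame from one of the detectors.
#' @param record_s Total duration of the analysed record(s), s.
#' @return List with `frequency_hz` (= count / record_s), `n_events`,
#'   `mean_duration_ms`, `median_duration_ms`, `mean_peak_force_pN`,
#'   `mean_displacement_nm`. Summaries are `NA` when no event was detected.
#' @export
event_stats <- function(events, record_s) {
  if (!is.numeric(record_s) || record_s <= 0) stop("record_s must be > 0")
  n <- nrow(events)
  if (n == 0) {
    return(list(frequency_hz = 0, n_events = 0L, mean_duration_ms = NA_real_,
                median_duration_ms = NA_real_,
                mean_peak_force_pN = NA_real_,
                mean_displacement_nm = NA_real_))
  }
  list(frequency_hz = n / record_s, n_events = as.integer(n),
       mean_duration_ms = mean(events$duration_ms),
       median_duration_ms = median(events$duration_ms),
       mean_peak_force_pN = mean(events$peak_force_pN),
       mean_displacement_nm = mean(events$displacement_nm))
}
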
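test_that("threshold detector applies both the 8 nm and 10 ms criteria", {
  dp <- detection_params()
  # square pulse 12 nm x 50 ms -> one event of about 50 ms
  ev <- detect_threshold(pulse_trace(12, 50), dp)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$duration_ms, 30)
  expect_lt(ev$duration_ms, 70)
  expect_equal(ev$displacement_nm, 12, tolerance = 0.15)
  expect_equal(ev$peak_force_pN, 0.04 * 12, tolerance = 0.02)
  # 6 nm is below the displacement threshold
  expect_equal(nrow(detect_threshold(pulse_trace(6, 50), dp)), 0)
  # 5 ms is below the duration threshold
  expect_equal(nrow(detect_threshold(pulse_trace(12, 5), dp)), 0)
  # pulses separated by a sub-threshold gap stay distinct
  ev2 <- detect_threshold(pulse_trace(c(15, 15), c(60, 60),
                                      t_start_s = c(1, 1.5)), dp)
  expect_equal(nrow(ev2), 2)
})

test_that("threshold detection is idempotent and time-shift invariant", {
  sch <- event_schedule(t_start_s = c(2, 6), duration_ms = c(80, 60),
                        displacement_nm = c(20, 25),
                        variance_scale = c(0.3, 0.3))
  tr <- make_trace(sch, seed = 21)
  ev <- detect_threshold(tr)
  expect_identical(detect_threshold(tr), ev)
  tr_shift <- tr
  tr_shift$t_s <- tr$t_s + 5
  ev_shift <- detect_threshold(tr_shift)
  expect_equal(ev_shift$t_start_s, ev$t_start_s + 5)
  expect_equal(ev_shift$duration_ms, ev$duration_ms)
})

test_that("shortening the duration threshold never decreases event count", {
  reg <- regulation_params(K_uM = 0.2)
  tr <- simulate_trace(mini_cfg(pca = 6))
  n10 <- nrow(detect_threshold(tr, detection_params(min_dur_ms = 10)))
  n5 <- nrow(detect_threshold(tr, detection_params(min_dur_ms = 5)))
  n20 <- nrow(detect_threshold(tr, detection_params(min_dur_ms = 20)))
  expect_gte(n5, n10)
  expect_gte(n10, n20)
})

test_that("variance-drop detector finds stiffened segments and guards its
          threshold", {
  sch <- event_schedule(t_start_s = 4, duration_ms = 40,
                        displacement_nm = 0, variance_scale = 0.25)
  tr <- make_trace(sch, seed = 31)
  ev <- detect_variance_drop(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_start_s, 4, tolerance = 0.02)
  expect_error(detection_params(var_drop_frac = 1), "var_drop_frac")
  short <- make_trace(duration_s = 0.03, seed = 1)
  expect_error(detect_variance_drop(short), "window")
})

test_that("Page detector locates attachment within 5 ms on labelled events", {
  sch <- event_schedule(t_start_s = c(2, 5, 8), duration_ms = rep(50, 3),
                        displacement_nm = rep(0, 3),
                        variance_scale = rep(0.25, 3))
  hits <- 0
  for (seed in 1:5) {
    tr <- make_trace(sch, seed = 600 + seed)
    ev <- detect_page(tr)
    for (ts in sch$t_start_s) {
      derr <- abs(ev$t_start_s - ts)
      if (any(derr < 0.005)) hits <- hits + 1
    }
  }
  expect_gte(hits / 15, 0.85)
})

test_that("all three detectors report zero events on motor-free baselines", {
  for (k_trap in c(0.0298, 0.0382)) {
    tr <- simulate_trace(trap_config(n_motors = 0, duration_s = 30,
                                     k_trap = k_trap,
                                     seed = round(k_trap * 1e4)))
    expect_equal(nrow(detect_threshold(tr)), 0)
    expect_equal(nrow(detect_variance_drop(tr)), 0)
    expect_equal(nrow(detect_page(tr)), 0)
  }
  # constant signal: no variance change, no events
  flat <- structure(data.frame(t_s = (1:8000) / 4000, x_nm = rep(5, 8000),
                               f_pN = rep(0.2, 8000)),
                    class = c("trap_trace", "data.frame"))
  expect_equal(nrow(detect_page(flat)), 0)
  expect_equal(nrow(detect_threshold(flat)), 0)
})

test_that("threshold detector recall and precision reach 0.9 at assay SNR", {
  starts <- seq(0.5, 9, by = 1.1)
  sch <- event_schedule(t_start_s = starts,
                        duration_ms = rep(60, length(starts)),
                        displacement_nm = rep(20, length(starts)),
                        variance_scale = rep(0.3, length(starts)))
  tp <- 0; fp <- 0; fn <- 0
  for (seed in 1:3) {
    tr <- make_trace(sch, seed = 800 + seed)
    ev <- detect_threshold(tr)
    matched <- rep(FALSE, nrow(ev))
    for (ts in starts) {
      j <- which(abs(ev$t_start_s - ts) < 0.04 & !matched)
      if (length(j) > 0) { tp <- tp + 1; matched[j[1]] <- TRUE }
      else fn <- fn + 1
    }
    fp <- fp + sum(!matched)
  }
  expect_gte(tp / (tp + fn), 0.9)
  expect_gte(tp / (tp + fp), 0.9)
})

test_that("event summaries follow the counting arithmetic", {
  ev41 <- data.frame(t_start_s = seq_len(41), duration_ms = rep(20, 41),
                     displacement_nm = rep(10, 41),
                     peak_force_pN = rep(0.4, 41))
  expect_equal(event_stats(ev41, 10)$frequency_hz, 4.1)
  ev594 <- data.frame(t_start_s = seq_len(594), duration_ms = rep(20, 594),
                      displacement_nm = rep(10, 594),
                      peak_force_pN = rep(0.4, 594))
  expect_equal(event_stats(ev594, 270)$frequency_hz, 2.2)
  empty <- event_stats(data.frame(t_start_s = numeric(0),
                                  duration_ms = numeric(0),
                                  displacement_nm = numeric(0),
                                  peak_force_pN = numeric(0)), 10)
  expect_equal(empty$frequency_hz, 0)
  expect_true(is.na(empty$mean_duration_ms))
  expect_error(event_stats(ev41, 0), "record_s")
})
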
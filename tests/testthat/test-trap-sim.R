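test_that("trap attachment-rate ladder returns 2.2 / 36 / 40", {
  p <- motor_params()
  expect_equal(attachment_rate_base(0, p), 2.2)
  expect_equal(attachment_rate_base(1, p), 36)
  expect_equal(attachment_rate_base(c(2, 3, 10), p), c(40, 40, 40))
  expect_error(attachment_rate_base(-1, p), ">= 0")
})

test_that("identical seed gives an identical trace", {
  cfg <- trap_config(n_motors = 1, duration_s = 2, seed = 7, pca = 5)
  t1 <- simulate_trace(cfg)
  t2 <- simulate_trace(cfg)
  expect_identical(t1$x_nm, t2$x_nm)
  expect_identical(attr(t1, "truth"), attr(t2, "truth"))
  t3 <- simulate_trace(trap_config(n_motors = 1, duration_s = 2, seed = 8,
                                   pca = 5))
  expect_false(identical(t1$x_nm, t3$x_nm))
})

test_that("motor-free baseline satisfies equipartition", {
  cfg <- trap_config(n_motors = 0, duration_s = 20, k_trap = 0.04,
                     seed = 11)
  tr <- simulate_trace(cfg)
  expect_equal(var(tr$x_nm), 4.14 / 0.04, tolerance = 0.05)
  expect_equal(sd(tr$x_nm), 10.17, tolerance = 0.05)
  # trap force column is k_trap * x elementwise
  expect_equal(tr$f_pN, 0.04 * tr$x_nm)
})

test_that("position variance drops while a motor is strongly bound", {
  cfg <- trap_config(n_motors = 1, atp_uM = 1, duration_s = 30, pca = 4,
                     seed = 12)
  reg_off <- regulation_params(eps_min = 1 - 1e-12, eps_max = 1)
  tr <- simulate_trace(cfg, reg_off)
  truth <- attr(tr, "truth")
  truth <- truth[truth$t_end_s - truth$t_start_s > 0.05, ]
  expect_gt(nrow(truth), 5)
  in_event <- rep(FALSE, nrow(tr))
  # variance within each event, about that event's own level (events sit at
  # different offsets, so pooling them would inflate the variance)
  v_ev <- vapply(seq_len(nrow(truth)), function(i) {
    idx <- tr$t_s >= truth$t_start_s[i] + 0.01 &
      tr$t_s <= truth$t_end_s[i] - 0.01
    in_event[idx] <<- TRUE
    var(tr$x_nm[idx])
  }, numeric(1))
  mp <- motor_params()
  ratio_expected <- cfg$k_trap / (cfg$k_trap + mp$k_m)
  ratio <- mean(v_ev) / var(tr$x_nm[!in_event])
  expect_lt(ratio, 2.5 * ratio_expected)
  expect_lt(ratio, 0.5)
})

test_that("unstable step sizes are rejected with guidance", {
  cfg <- trap_config(n_motors = 1, atp_uM = 4000)
  expect_error(simulate_trace(cfg), "dt")
})

test_that("single-molecule attachment rate recovers epsilon across calcium", {
  reg <- regulation_params(K_uM = 0.216)
  for (p in c(4, 6, 7)) {
    f <- single_molecule_frequency(p, reg, n_events_target = 50,
                                   max_time_s = 400, seed = 40 + p)
    eps <- epsilon_ca(pca_to_conc(p), reg)
    rel_se <- 1 / sqrt(f$n_events)
    expect_false(f$upper_bound)
    expect_lt(abs(f$relative - eps), 2 * rel_se * eps + 0.02 * eps)
  }
})

test_that("detected event frequency increases with calcium", {
  reg <- regulation_params()
  f7 <- single_molecule_frequency(7, reg, n_events_target = 25,
                                  max_time_s = 300, seed = 71)
  f5 <- single_molecule_frequency(5, reg, n_events_target = 25,
                                  max_time_s = 300, seed = 72)
  expect_gt(f5$frequency_hz, f7$frequency_hz)
})

test_that("with eps_min = eps_max the trap output is calcium-independent", {
  reg_flat <- regulation_params(eps_min = 0.5, eps_max = 0.5)
  cfg9 <- trap_config(n_motors = 1, atp_uM = 1, duration_s = 60, pca = 9,
                      seed = 13)
  cfg4 <- trap_config(n_motors = 1, atp_uM = 1, duration_s = 60, pca = 4,
                      seed = 13)
  n9 <- nrow(attr(simulate_trace(cfg9, reg_flat), "truth"))
  n4 <- nrow(attr(simulate_trace(cfg4, reg_flat), "truth"))
  # same seed, identical rates: the event sequence must coincide exactly
  expect_identical(n9, n4)
})

test_that("mini-ensemble event peak force and lifetime are correlated", {
  reg <- regulation_params(K_uM = 0.2)
  set.seed(91)
  cfg <- mini_cfg(pca = 5)
  ev <- do.call(rbind, lapply(1:8, function(k)
    detect_threshold(simulate_trace(cfg, reg))))
  expect_gt(nrow(ev), 100)
  expect_gt(cor(ev$peak_force_pN, ev$duration_ms), 0.3)
})
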
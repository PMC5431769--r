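test_that("Hill fit recovers noiseless parameters to 4 significant figures", {
  pca <- seq(4.5, 8, by = 0.5)
  conc <- pca_to_conc(pca)
  y <- 0.1 + 0.8 * conc^2 / (1^2 + conc^2) # alpha = 2, pCa50 = 6
  h <- fit_hill(pca, y)
  expect_true(h$converged)
  expect_equal(h$alpha, 2, tolerance = 1e-4)
  expect_equal(h$pca50, 6, tolerance = 1e-4)
  expect_equal(h$amplitude, 0.8, tolerance = 1e-4)
  expect_equal(h$baseline, 0.1, tolerance = 1e-4)
  expect_lt(h$residual_ss, 1e-8 * sum(y^2))
  expect_error(fit_hill(c(4, 5, 6), c(1, 2, 3)), ">= 4")
})

test_that("K fit is exact on noiseless model curves", {
  reg <- regulation_params()
  for (K_true in c(0.15, 0.216)) {
    g <- data.frame(pca = c(4, 5, 6, 7, 9))
    g$rel_freq <- epsilon_ca(pca_to_conc(g$pca),
                             regulation_params(K_uM = K_true))
    fit <- fit_K(g, reg)
    expect_equal(fit$K_uM, K_true, tolerance = 1e-4)
    expect_false(fit$boundary)
  }
  # with stated uncertainties a perfect fit has chi2 ~ 0, p ~ 1
  g <- data.frame(pca = c(4, 5, 6, 7, 9))
  g$rel_freq <- epsilon_ca(pca_to_conc(g$pca),
                           regulation_params(K_uM = 0.216))
  g$sd <- 0.1 * g$rel_freq
  fit <- fit_K(g, regulation_params())
  expect_lt(fit$chi2, 1e-6)
  expect_gt(fit$p_value, 0.999)
  expect_equal(fit$dof, 4)
})

test_that("fits are invariant to record ordering", {
  g <- make_activation_curve(seed = 5)$curve
  shuffled <- g[sample(nrow(g)), ]
  expect_equal(fit_K(g)$K_uM, fit_K(shuffled)$K_uM)
  h1 <- fit_hill(g$pca, g$rel_freq, g$sd)
  h2 <- fit_hill(shuffled$pca, shuffled$rel_freq, shuffled$sd)
  expect_equal(h1$pca50, h2$pca50)
  expect_equal(h1$alpha, h2$alpha)
})

test_that("K estimator is median-unbiased with quartiles near the
          experimental scale", {
  set.seed(42)
  reg <- regulation_params(K_uM = 0.2)
  est <- vapply(1:300, function(b)
    fit_K(make_activation_curve(reg = reg)$curve, reg)$K_uM, numeric(1))
  expect_lt(abs(median(est) - 0.2), 0.02) # within 10%
  expect_gte(mean(abs(est - 0.2) <= 0.06), 0.8)
  iqr <- diff(quantile(est, c(0.25, 0.75), names = FALSE))
  expect_gt(iqr / 2, 0.015)
  expect_lt(iqr / 2, 0.08)
})

test_that("chi-square p-values are uniform under the null", {
  set.seed(43)
  reg <- regulation_params(K_uM = 0.2)
  pca <- c(4, 5, 6, 7, 9)
  eps <- epsilon_ca(pca_to_conc(pca), reg)
  sdv <- 0.2 * eps
  p <- vapply(1:300, function(b) {
    g <- data.frame(pca = pca, rel_freq = rnorm(5, eps, sdv), sd = sdv)
    fit_K(g, reg)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("bootstrap of K is reproducible and degenerates sensibly", {
  g <- make_activation_curve(n_records = 5, seed = 7)
  b1 <- bootstrap_K(g$records, n_boot = 200, seed = 8)
  b2 <- bootstrap_K(g$records, n_boot = 200, seed = 8)
  expect_identical(b1$estimates, b2$estimates)
  expect_lt(abs(b1$median - 0.2), 0.06)
  # all records identical within each pCa -> zero quartile width
  recs <- data.frame(pca = rep(c(4, 5, 6, 7, 9), each = 3),
                     rel_freq = rep(epsilon_ca(pca_to_conc(c(4, 5, 6, 7, 9)),
                                               regulation_params()),
                                    each = 3))
  suppressWarnings(b0 <- bootstrap_K(recs, n_boot = 120, seed = 9))
  expect_equal(b0$upper_quartile - b0$lower_quartile, 0)
  expect_warning(bootstrap_K(g$records, n_boot = 50, seed = 1), "n_boot")
  expect_error(bootstrap_K(data.frame(pca = c(4, 5), rel_freq = c(1, 2))),
               "2 records")
})

test_that("epsilon is recovered from motility speed-ATP data", {
  set.seed(21)
  mp <- motor_params()
  r_true <- regulation_params(0.1, 0.1, 0.2)
  atp <- c(20, 45, 80, 150, 300, 600)
  cfg <- motility_config()
  obs <- data.frame(atp_uM = atp, mean_speed_um_s = vapply(atp, function(a) {
    cfg$atp_uM <- a
    mean(vapply(1:3, function(k) simulate_motility(cfg, r_true, mp)$speed_um_s,
                numeric(1)))
  }, numeric(1)))
  fe <- fit_epsilon_per_condition(obs, cfg, regulation_params(), mp,
                                  seed = 22)
  expect_false(fe$unidentifiable)
  expect_lt(max(fe$eps / 0.1, 0.1 / fe$eps), 1.3)
})

test_that("epsilon is unidentifiable when all ATP points sit below the
          critical concentration", {
  # below the breakpoint speed is calcium-independent, so the objective is
  # flat in eps
  obs <- data.frame(atp_uM = c(5, 10, 20),
                    mean_speed_um_s = c(5, 10, 20) * 0.03)
  fe <- fit_epsilon_per_condition(obs, motility_config(),
                                  regulation_params(), motor_params(),
                                  replicates = 2, n_grid = 5, seed = 23)
  expect_true(fe$unidentifiable)
})

test_that("the coupling-distance scan requires a usable grid", {
  expect_error(ell_sensitivity(list(), ell_grid = c(100, 400, 800)),
               ">= 4")
})
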
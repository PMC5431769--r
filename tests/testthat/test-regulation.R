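test_that("pCa-concentration conversion matches its definition and round-trips", {
  expect_equal(pca_to_conc(6), 1)
  expect_equal(pca_to_conc(4), 100)
  expect_equal(pca_to_conc(9), 0.001)
  pcas <- seq(3, 10, by = 0.25)
  expect_equal(conc_to_pca(pca_to_conc(pcas)), pcas)
  expect_error(pca_to_conc(NA_real_), "finite")
  expect_error(pca_to_conc(Inf), "finite")
  expect_error(conc_to_pca(-1), "positive")
})

test_that("troponin saturation is Michaelis-Menten", {
  expect_equal(theta_ca(0, 0.2), 0)
  expect_equal(theta_ca(0.2, 0.2), 0.5)
  expect_equal(theta_ca(1, 0.2), 1 / 1.2)
  expect_error(theta_ca(-0.1, 0.2), ">= 0")
  expect_error(theta_ca(1, 0), "> 0")
  conc <- c(0, 10^seq(-4, 3, by = 0.5))
  th <- theta_ca(conc, 0.2)
  expect_true(all(diff(th) > 0))
  expect_true(all(th >= 0 & th < 1))
})

test_that("relative attachment rate interpolates geometrically with calcium", {
  reg <- regulation_params()
  expect_equal(epsilon_ca(0, reg), reg$eps_min)
  expect_equal(epsilon_ca(reg$K_uM, reg), sqrt(reg$eps_min * reg$eps_max))
  expect_equal(epsilon_ca(reg$K_uM, reg), 0.0547723, tolerance = 1e-6)
  # direct evaluation at saturating calcium, K = 0.216
  reg216 <- regulation_params(K_uM = 0.216)
  th <- 100 / (0.216 + 100)
  expect_equal(epsilon_ca(100, reg216), 0.006^(1 - th) * 0.5^th)
  expect_equal(epsilon_ca(100, reg216), 0.4953, tolerance = 1e-3)
})

test_that("epsilon is continuous, monotone, bounded, and log-affine in theta", {
  reg <- regulation_params()
  conc <- 10^seq(-5, 4, length.out = 200)
  eps <- epsilon_ca(conc, reg)
  expect_true(all(diff(eps) > 0))
  expect_true(all(eps >= reg$eps_min & eps <= reg$eps_max))
  expect_equal(epsilon_ca(1e-12, reg), reg$eps_min, tolerance = 1e-6)
  expect_equal(epsilon_ca(1e12, reg), reg$eps_max, tolerance = 1e-6)
  # log eps(theta) - log eps_min = theta * (log eps_max - log eps_min)
  th <- theta_ca(conc, reg$K_uM)
  expect_equal(log(eps) - log(reg$eps_min),
               th * (log(reg$eps_max) - log(reg$eps_min)),
               tolerance = 1e-12)
})

test_that("activation factor implements the none/one/both-sides rule", {
  reg <- regulation_params(ell_nm = 400, partial_exponent = 0.5)
  pos <- c(-200, 0, 200)
  # no bound motor within ell -> eps
  expect_equal(activation_factor(pos, c(FALSE, FALSE, FALSE), 2, 0.04, reg),
               0.04)
  # flanked at +/-200 nm -> full activation
  expect_equal(activation_factor(pos, c(TRUE, FALSE, TRUE), 2, 0.04, reg), 1)
  # one bound neighbour at 300 nm -> eps^0.5
  expect_equal(activation_factor(c(0, 300), c(FALSE, TRUE), 1, 0.04, reg),
               0.2)
  # strictly-less-than ell counts as within: a neighbour at exactly ell does
  # not activate
  expect_equal(activation_factor(c(0, 400), c(FALSE, TRUE), 1, 0.04, reg),
               0.04)
  expect_error(activation_factor(pos, c(TRUE, FALSE, TRUE), 5, 0.04, reg),
               "out of range")
})

test_that("activation factor is bounded and collapses to eps when ell = 0", {
  set.seed(1)
  reg0 <- regulation_params(ell_nm = 0)
  reg <- regulation_params()
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    pos <- sort(runif(n, -600, 600))
    bound <- runif(n) < 0.4
    bound[sample(n, 1)] <- FALSE # keep at least one detached motor
    free <- which(!bound)
    i <- free[sample.int(length(free), 1)]
    eps <- runif(1, 0.006, 0.5)
    f <- activation_factor(pos, bound, i, eps, reg)
    expect_gte(f, eps)
    expect_lte(f, 1)
    expect_identical(activation_factor(pos, bound, i, eps, reg0), eps)
    # invariant under translation of all coordinates
    expect_equal(activation_factor(pos + 123.4, bound, i, eps, reg), f)
  }
})

test_that("regulation parameter validation rejects inconsistent values", {
  expect_error(regulation_params(eps_min = 0), "eps_min")
  expect_error(regulation_params(eps_min = 0.6, eps_max = 0.5), "eps_min")
  expect_error(regulation_params(K_uM = -1), "K_uM")
  expect_error(regulation_params(ell_nm = -5), "ell_nm")
  expect_error(regulation_params(partial_exponent = 1.5), "partial_exponent")
})
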
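#' Hill fit of an activation or force-pCa curve
#'
#' Weighted least-squares fit of
#' `y = base + amp * C^alpha / (C50^alpha + C^alpha)` with `C` the calcium
#' concentration (uM). The fit variable is concentration, not pCa, and a
#' baseline term is included because single-molecule binding does not vanish
#' in the absence of calcium. Multi-start over the Hill coefficient avoids
#' local minima.
#'
#' @param pca pCa values (>= 4 distinct points spanning the transition).
#' @param y Response (relative frequency or normalised force).
#' @param sd Optional per-point standard deviations; weights are `1/sd^2`.
#' @param starts_alpha Hill-coefficient starting values
#'   (default `c(0.5, 1, 2, 4)`).
#' @return An object of class `hill_fit`: list with `pca50`, `alpha`,
#'   `amplitude`, `baseline`, `se` (named vector of parameter SDs),
#'   `converged`, `residual_ss`, and the fitted `model`.
#' @export
fit_hill <- function(pca, y, sd = NULL, starts_alpha = c(0.5, 1, 2, 4)) {
  ok <- is.finite(pca) & is.finite(y)
  pca <- pca[ok]; y <- y[ok]
  if (!is.null(sd)) sd <- sd[ok]
  if (length(unique(pca)) < 4)
    stop("need >= 4 distinct pCa points")
  conc <- pca_to_conc(pca)
  w <- if (is.null(sd)) rep(1, length(y)) else {
    if (any(!is.finite(sd)) || any(sd < 0)) stop("sd must be >= 0")
    if (any(sd == 0)) {
      warning("zero sd supplied; falling back to unweighted fit")
      rep(1, length(y))
    } else 1 / sd^2
  }
  dat <- data.frame(conc = conc, y = y)
  c50_start <- exp(approx_c50(conc, y))
  best <- NULL
  for (a0 in starts_alpha) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ base + amp * conc^alpha / (c50^alpha + conc^alpha),
        data = dat, weights = w,
        start = list(base = max(min(y), 1e-6), amp = diff(range(y)),
                     c50 = c50_start, alpha = a0),
        lower = c(base = 0, amp = 1e-12, c50 = 1e-6, alpha = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(pca50 = NA_real_, alpha = NA_real_,
                          amplitude = NA_real_, baseline = NA_real_,
                          se = NULL, converged = FALSE,
                          residual_ss = NA_real_, model = NULL),
                     class = "hill_fit"))
  }
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e)
    stats::setNames(rep(NA_real_, 4), names(cf)))
  # d pCa50 / d log10(c50) = -1, so SD propagates directly
  se_pca50 <- unname(se["c50"] / (cf[["c50"]] * log(10)))
  structure(list(pca50 = conc_to_pca(cf[["c50"]]), alpha = cf[["alpha"]],
                 amplitude = cf[["amp"]], baseline = cf[["base"]],
                 se = c(pca50 = se_pca50, alpha = unname(se["alpha"]),
                        amplitude = unname(se["amp"]),
                        baseline = unname(se["base"])),
                 converged = TRUE, residual_ss = best$rss,
                 model = best$fit),
            class = "hill_fit")
}

# crude log-C50 start: concentration where y crosses its mid-range
approx_c50 <- function(conc, y) {
  o <- order(conc)
  conc <- conc[o]; y <- y[o]
  mid <- (max(y) + min(y)) / 2
  i <- which(y >= mid)[1]
  if (is.na(i) || i == 1) return(log(stats::median(conc)))
  log(sqrt(conc[i] * conc[i - 1]))
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Hill fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("Hill fit: pCa50 = %.3f +/- %.3f, alpha = %.3f +/- %.3f\n",
              x$pca50, x$se["pca50"], x$alpha, x$se["alpha"]))
  cat(sprintf("  amplitude = %.4g, baseline = %.4g, weighted RSS = %.4g\n",
              x$amplitude, x$baseline, x$residual_ss))
  invisible(x)
}

#' Fit the troponin Michaelis constant K to an activation curve
#'
#' One-dimensional weighted least squares over `K` with `eps_min` and
#' `eps_max` held fixed a priori: the model prediction at each pCa is
#' the relative rate \eqn{\varepsilon([Ca]; K)}. Goodness of fit is the
#' chi-square statistic `sum(((obs - pred)/sd)^2)` with `n - 1` degrees of
#' freedom and an upper-tail p-value.
#'
#' @param curve Data frame with columns `pca`, `rel_freq` and optionally
#'   `sd` (one row per pCa).
#' @param reg A [regulation_params()] object fixing `eps_min`/`eps_max`.
#' @param K_range Search interval for K, uM (default `c(1e-3, 1e2)`).
#' @return An object of class `k_fit`: list with `K_uM`, `chi2`, `dof`,
#'   `p_value`, `boundary` (TRUE if the optimum sits on the search
#'   boundary), `weighted`.
#' @export
fit_K <- function(curve, reg = regulation_params(), K_range = c(1e-3, 1e2)) {
  stopifnot(all(c("pca", "rel_freq") %in% names(curve)))
  conc <- pca_to_conc(curve$pca)
  obs <- curve$rel_freq
  sdv <- curve$sd
  weighted <- TRUE
  if (is.null(sdv) || any(!is.finite(sdv)) || any(sdv == 0)) {
    if (!is.null(sdv)) warning("zero or missing sd; using unweighted fit")
    sdv <- rep(1, length(obs))
    weighted <- FALSE
  }
  obj <- function(logK) {
    r2 <- regulation_params(reg$eps_min, reg$eps_max, exp(logK),
                            reg$ell_nm, reg$partial_exponent)
    sum(((obs - epsilon_ca(conc, r2)) / sdv)^2)
  }
  opt <- optimize(obj, log(K_range), tol = 1e-10)
  K <- exp(opt$minimum)
  boundary <- min(abs(log(K / K_range))) < 1e-3
  chi2 <- opt$objective
  dof <- length(obs) - 1
  structure(list(K_uM = K, chi2 = chi2, dof = dof,
                 p_value = if (weighted)
                   pchisq(chi2, dof, lower.tail = FALSE) else NA_real_,
                 boundary = boundary, weighted = weighted),
            class = "k_fit")
}

#' @export
print.k_fit <- function(x, ...) {
  cat(sprintf("K fit: K = %.4g uM (chi2 = %.3g on %d dof, p = %.3g)%s\n",
              x$K_uM, x$chi2, x$dof, x$p_value,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Bootstrap uncertainty of the Michaelis constant K
#'
#' Resamples individual records (the ~10-s trap recordings, the finest unit
#' of the experiment) with replacement within each pCa, refits K to the
#' per-pCa means and SDs of each resample, and summarises the replicate
#' estimates by their median and quartiles.
#'
#' @param records Data frame with columns `pca` and `rel_freq`, one row per
#'   recording (>= 2 records per pCa).
#' @param reg A [regulation_params()] object fixing `eps_min`/`eps_max`.
#' @param n_boot Number of bootstrap replicates (default 1000; < 100 warns).
#' @param seed Optional seed; results are reproducible for a fixed seed.
#' @return List with `median`, `lower_quartile`, `upper_quartile`,
#'   `estimates` (all replicate K values) and `n_skipped` (degenerate
#'   resamples).
#' @export
bootstrap_K <- function(records, reg = regulation_params(), n_boot = 1000,
                        seed = NULL) {
  stopifnot(all(c("pca", "rel_freq") %in% names(records)))
  if (n_boot < 100) warning("n_boot < 100: quartiles will be noisy")
  if (!is.null(seed)) set.seed(seed)
  groups <- split(records$rel_freq, records$pca)
  if (any(lengths(groups) < 2))
    stop("need >= 2 records per pCa for resampling")
  pcas <- as.numeric(names(groups))
  est <- rep(NA_real_, n_boot)
  n_skipped <- 0L
  for (b in seq_len(n_boot)) {
    means <- numeric(length(groups))
    sds <- numeric(length(groups))
    for (g in seq_along(groups)) {
      v <- sample(groups[[g]], replace = TRUE)
      means[g] <- mean(v)
      sds[g] <- sd(v)
    }
    if (length(unique(pcas)) < 2) {
      n_skipped <- n_skipped + 1L
      next
    }
    cv <- data.frame(pca = pcas, rel_freq = means,
                     sd = ifelse(sds > 0, sds, NA_real_))
    if (any(!is.finite(cv$sd))) cv$sd <- NULL
    est[b] <- suppressWarnings(fit_K(cv, reg)$K_uM)
  }
  est_ok <- est[is.finite(est)]
  q <- quantile(est_ok, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], lower_quartile = q[1], upper_quartile = q[3],
       estimates = est_ok, n_skipped = n_skipped)
}

#' Estimate the relative attachment rate from motility data at one calcium
#' level
#'
#' Searches over \eqn{\varepsilon} (calcium held implicit: the simulator is
#' run with `eps_min = eps_max = eps`, i.e. a calcium-independent relative
#' rate) for the value that minimises the squared error between simulated
#' and observed mean speeds across the ATP grid. The search is a log-spaced
#' grid followed by parabolic refinement; the uncertainty is read off the
#' curvature of the objective profile.
#'
#' @param speeds Data frame with columns `atp_uM` and `mean_speed_um_s`
#'   (one pCa condition).
#' @param cfg Template [motility_config()].
#' @param reg Template [regulation_params()] (supplies `ell_nm` and the
#'   search bounds `eps_min`, `eps_max`).
#' @param mp A [motor_params()] object.
#' @param replicates Simulator replicates per (eps, ATP) cell (default 3).
#' @param n_grid Number of log-grid points (default 9).
#' @param seed Optional seed.
#' @return List with `eps`, `sd`, `objective` (data frame of the profile),
#'   and `unidentifiable` (TRUE when the profile is flat, i.e. all ATP
#'   points sit below the critical concentration where speed is
#'   calcium-independent).
#' @export
fit_epsilon_per_condition <- function(speeds, cfg = motility_config(),
                                      reg = regulation_params(),
                                      mp = motor_params(), replicates = 3,
                                      n_grid = 9, seed = NULL) {
  stopifnot(all(c("atp_uM", "mean_speed_um_s") %in% names(speeds)))
  if (!is.null(seed)) set.seed(seed)
  eps_grid <- exp(seq(log(reg$eps_min), log(reg$eps_max),
                      length.out = n_grid))
  sim_speed <- function(eps, atp) {
    r2 <- regulation_params(eps, eps, reg$K_uM, reg$ell_nm,
                            reg$partial_exponent)
    mean(vapply(seq_len(replicates), function(k) {
      cfg$atp_uM <- atp
      cfg$seed <- NULL
      simulate_motility(cfg, r2, mp)$speed_um_s
    }, numeric(1)))
  }
  pred <- vapply(eps_grid, function(e)
    vapply(speeds$atp_uM, function(a) sim_speed(e, a), numeric(1)),
    numeric(nrow(speeds)))
  pred <- matrix(pred, nrow = nrow(speeds))
  obj <- colSums((pred - speeds$mean_speed_um_s)^2)
  prof <- data.frame(eps = eps_grid, sse = obj)
  # flat objective: the simulated speeds barely vary with eps (all ATP
  # points below the critical concentration)
  spread <- apply(pred, 1, function(v) diff(range(v)) / max(mean(v), 1e-9))
  if (max(spread) < 0.1) {
    return(list(eps = NA_real_, sd = NA_real_, objective = prof,
                unidentifiable = TRUE))
  }
  i <- which.min(obj)
  le <- log(eps_grid)
  if (i > 1 && i < length(obj)) {
    # parabolic refinement + curvature-based SD in log eps
    d1 <- (obj[i + 1] - obj[i - 1]) / (le[i + 1] - le[i - 1])
    d2 <- (obj[i + 1] - 2 * obj[i] + obj[i - 1]) /
      ((le[i + 1] - le[i])^2)
    le_hat <- if (d2 > 0) le[i] - d1 / d2 else le[i]
    le_hat <- min(max(le_hat, le[1]), le[length(le)])
    sigma2 <- obj[i] / max(length(speeds$atp_uM) - 1, 1)
    sd_log <- if (d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  } else {
    le_hat <- le[i]
    sd_log <- NA_real_
  }
  eps_hat <- exp(le_hat)
  list(eps = eps_hat, sd = if (is.finite(sd_log)) eps_hat * sd_log else
    NA_real_, objective = prof, unidentifiable = FALSE)
}

#' Sensitivity of the model fit to the coupling distance
#'
#' For each candidate coupling distance, refits K to the single-molecule
#' activation curve (which is independent of the coupling) and compares
#' model-simulated mini-ensemble event frequencies and motility speeds to
#' the supplied datasets, returning the combined chi-square objective. The
#' acceptance interval is the set of distances whose objective lies within
#' the chi-square 95% quantile (1 dof) of the minimum.
#'
#' @param datasets List with any of: `activation` (data frame `pca`,
#'   `rel_freq`, `sd`), `mini` (data frame `pca`, `freq_hz`, `sd`), and
#'   `motility` (data frame `pca`, `atp_uM`, `mean_speed_um_s`, `sd`).
#' @param ell_grid Candidate coupling distances, nm (>= 4 points).
#' @param reg,mp Template parameter objects.
#' @param trap_cfg Template [trap_config()] for the mini-ensemble
#'   simulations.
#' @param mot_cfg Template [motility_config()].
#' @param dp [detection_params()] used to score simulated mini traces.
#' @param traces_per_pca Simulated 10-s mini-ensemble traces per pCa
#'   (default 8).
#' @param replicates Motility replicates per condition (default 3).
#' @param seed Optional seed.
#' @return List with `profile` (data frame `ell_nm`, `chisq`), `ell_best`,
#'   `interval` (range of grid distances within the 95% band).
#' @export
ell_sensitivity <- function(datasets, ell_grid, reg = regulation_params(),
                            mp = motor_params(),
                            trap_cfg = trap_config(k_trap = 0.038,
                                                   n_motors = 14),
                            mot_cfg = motility_config(),
                            dp = detection_params(),
                            traces_per_pca = 8, replicates = 3,
                            seed = NULL) {
  if (length(ell_grid) < 4) stop("ell_grid must have >= 4 points")
  if (!is.null(seed)) set.seed(seed)
  chisq <- vapply(ell_grid, function(ell) {
    r <- regulation_params(reg$eps_min, reg$eps_max, reg$K_uM, ell,
                           reg$partial_exponent)
    if (!is.null(datasets$activation))
      r$K_uM <- fit_K(datasets$activation, r)$K_uM
    total <- 0
    if (!is.null(datasets$mini)) {
      for (j in seq_len(nrow(datasets$mini))) {
        trap_cfg$pca <- datasets$mini$pca[j]
        trap_cfg$seed <- NULL
        n_ev <- 0
        for (k in seq_len(traces_per_pca))
          n_ev <- n_ev + nrow(detect_threshold(simulate_trace(trap_cfg, r,
                                                              mp), dp))
        pred <- n_ev / (traces_per_pca * trap_cfg$duration_s)
        total <- total +
          ((pred - datasets$mini$freq_hz[j]) / datasets$mini$sd[j])^2
      }
    }
    if (!is.null(datasets$motility)) {
      for (j in seq_len(nrow(datasets$motility))) {
        mot_cfg$pca <- datasets$motility$pca[j]
        mot_cfg$atp_uM <- datasets$motility$atp_uM[j]
        mot_cfg$seed <- NULL
        pred <- mean(vapply(seq_len(replicates), function(k)
          simulate_motility(mot_cfg, r, mp)$speed_um_s, numeric(1)))
        total <- total + ((pred - datasets$motility$mean_speed_um_s[j]) /
                            datasets$motility$sd[j])^2
      }
    }
    total
  }, numeric(1))
  profile <- data.frame(ell_nm = ell_grid, chisq = chisq)
  best <- which.min(chisq)
  band <- chisq <= chisq[best] + stats::qchisq(0.95, 1)
  list(profile = profile, ell_best = ell_grid[best],
       interval = range(ell_grid[band]))
}
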
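#' Ground-truth event schedule for synthetic traces
#'
#' @param t_start_s Event start times, s.
#' @param duration_ms Event durations, ms.
#' @param displacement_nm Mean bead displacement during each event, nm.
#' @param variance_scale Factor (in `(0, 1]`) applied to the position
#'   variance during each event (a strongly bound motor stiffens the
#'   dumbbell and reduces the thermal variance).
#' @return Data frame of class `event_schedule`.
#' @export
event_schedule <- function(t_start_s = numeric(0), duration_ms = numeric(0),
                           displacement_nm = numeric(0),
                           variance_scale = numeric(0)) {
  n <- length(t_start_s)
  if (length(duration_ms) != n || length(displacement_nm) != n ||
      length(variance_scale) != n)
    stop("all schedule fields must have the same length")
  if (any(variance_scale <= 0 | variance_scale > 1))
    stop("variance_scale must be in (0, 1]")
  sch <- data.frame(t_start_s = t_start_s, duration_ms = duration_ms,
                    displacement_nm = displacement_nm,
                    variance_scale = variance_scale)
  sch <- sch[order(sch$t_start_s), , drop = FALSE]
  ends <- sch$t_start_s + sch$duration_ms / 1000
  if (n > 1 && any(sch$t_start_s[-1] < ends[-n]))
    stop("events must not overlap")
  class(sch) <- c("event_schedule", "data.frame")
  sch
}

#' Generate a synthetic trap trace with scheduled events
#'
#' The baseline is an Ornstein-Uhlenbeck process with stationary variance
#' `kBT / k_trap` (the equipartition value) and relaxation rate
#' `k_trap / gamma` (a trapped bead has a Lorentzian spectrum, not white
#' noise). During each scheduled event the mean is offset by the event
#' displacement and the variance is multiplied by its `variance_scale`
#' (implemented as a proportionally stiffer effective spring). The schedule
#' is returned as ground-truth labels.
#'
#' @param schedule An [event_schedule()].
#' @param k_trap Trap stiffness, pN/nm (default 0.04).
#' @param kBT Thermal energy, pN nm (default 4.14).
#' @param gamma Drag coefficient, pN s/nm (default 7.5e-6, the Stokes drag of a 1-um bead in water at 30 C).
#' @param sample_hz Sampling rate, Hz (default 4000).
#' @param duration_s Trace length, s (default 10).
#' @param seed Optional seed (recorded in the metadata; same seed, same
#'   trace).
#' @return A `trap_trace` data frame (`t_s`, `x_nm`, `f_pN`) with `truth`
#'   and `meta` attributes.
#' @export
make_trace <- function(schedule = event_schedule(), k_trap = 0.04,
                       kBT = 4.14, gamma = 7.5e-6, sample_hz = 4000,
                       duration_s = 10, seed = NULL) {
  stopifnot(inherits(schedule, "event_schedule"))
  if (k_trap <= 0 || kBT <= 0 || gamma <= 0)
    stop("k_trap, kBT and gamma must be > 0")
  if (nrow(schedule) > 0 &&
      any(schedule$t_start_s + schedule$duration_ms / 1000 > duration_s))
    stop("schedule extends past the trace duration")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration_s * sample_hz))
  t <- seq_len(n) / sample_hz
  # per-sample effective stiffness and mean
  k_eff <- rep(k_trap, n)
  mu <- rep(0, n)
  for (j in seq_len(nrow(schedule))) {
    idx <- which(t >= schedule$t_start_s[j] &
                   t < schedule$t_start_s[j] + schedule$duration_ms[j] / 1000)
    k_eff[idx] <- k_trap / schedule$variance_scale[j]
    mu[idx] <- schedule$displacement_nm[j]
  }
  dt <- 1 / sample_hz
  a <- exp(-k_eff * dt / gamma)
  s <- sqrt(kBT / k_eff * (1 - a^2))
  x <- numeric(n)
  xprev <- rnorm(1, 0, sqrt(kBT / k_trap))
  innov <- rnorm(n)
  for (i in seq_len(n)) {
    xprev <- mu[i] + (xprev - mu[i]) * a[i] + s[i] * innov[i]
    x[i] <- xprev
  }
  tr <- data.frame(t_s = t, x_nm = x, f_pN = k_trap * x)
  attr(tr, "meta") <- list(cfg = list(k_trap = k_trap, kBT = kBT,
                                      gamma = gamma, sample_hz = sample_hz,
                                      duration_s = duration_s, seed = seed,
                                      generator = "make_trace"),
                           sample_hz_actual = sample_hz)
  attr(tr, "truth") <- schedule
  class(tr) <- c("trap_trace", "data.frame")
  tr
}

#' Generate a synthetic single-molecule activation curve
#'
#' Evaluates the regulation model \eqn{\varepsilon([Ca])} at the requested
#' pCa values and emulates replicate recordings with multiplicative noise:
#' each record's relative frequency is normal with mean \eqn{\varepsilon}
#' and standard deviation `cv * eps` (truncated at zero). The defaults
#' mirror the published experiment: a handful of ~10-s records per calcium
#' level with record-to-record scatter of about 40%.
#'
#' @param pca pCa values (default `c(4, 5, 6, 7, 9)`).
#' @param reg A [regulation_params()] object (the generating truth).
#' @param cv Coefficient of variation of a single record (default 0.39).
#' @param n_records Records per pCa (default 3).
#' @param seed Optional seed.
#' @return List with `curve` (data frame `pca`, `rel_freq` = mean over
#'   records, `sd` = the generator's record-level SD `cv * eps`, i.e. the
#'   error bar a figure would print, `n`) and `records` (record-level data
#'   frame for bootstrap resampling), plus the generating parameters.
#' @export
make_activation_curve <- function(pca = c(4, 5, 6, 7, 9),
                                  reg = regulation_params(), cv = 0.39,
                                  n_records = 3, seed = NULL) {
  if (cv < 0) stop("cv must be >= 0")
  if (n_records < 1) stop("n_records must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  eps <- epsilon_ca(pca_to_conc(pca), reg)
  recs <- do.call(rbind, lapply(seq_along(pca), function(i) {
    v <- pmax(rnorm(n_records, eps[i], cv * eps[i]), 0)
    data.frame(pca = pca[i], rel_freq = v)
  }))
  curve <- do.call(rbind, lapply(seq_along(pca), function(i) {
    d <- recs[recs$pca == pca[i], ]
    data.frame(pca = pca[i], rel_freq = mean(d$rel_freq),
               sd = cv * eps[i], n = nrow(d))
  }))
  rownames(curve) <- NULL
  list(curve = curve, records = recs, reg = reg, cv = cv,
       n_records = n_records, seed = seed)
}
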
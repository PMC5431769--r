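#' Laser-trap simulation configuration
#'
#' Settings for the three-bead assay simulation. The bead-actin-bead
#' dumbbell is reduced to one effective coordinate held by the combined trap
#' stiffness; `n_motors` heads with anchors spaced `anchor_spacing_nm` apart
#' can interact with the filament.
#'
#' @param k_trap Trap stiffness, pN/nm (default 0.04).
#' @param gamma Drag coefficient of the dumbbell, pN s/nm (default 7.5e-6,
#'   the Stokes drag of a 1-um bead in water at 30 C).
#' @param dt Integration step, s (default 25e-6).
#' @param sample_hz Output sampling rate, Hz (default 4000).
#' @param duration_s Trace length, s (default 10).
#' @param n_motors Number of available heads (1 for single molecule, ~14 for
#'   a mini-ensemble; 0 generates a motor-free baseline record).
#' @param atp_uM ATP concentration, uM (default 100).
#' @param pca Calcium level as pCa (default 9).
#' @param anchor_spacing_nm Spacing between motor anchors along the filament
#'   axis, nm (default 36, about one actin pseudo-repeat).
#' @param seed Optional RNG seed recorded in the trace metadata.
#' @return An object of class `trap_config`.
#' @export
trap_config <- function(k_trap = 0.04, gamma = 7.5e-6, dt = 25e-6,
                        sample_hz = 4000, duration_s = 10, n_motors = 1,
                        atp_uM = 100, pca = 9, anchor_spacing_nm = 36,
                        seed = NULL) {
  if (k_trap <= 0) stop("k_trap must be > 0")
  if (gamma <= 0) stop("gamma must be > 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (n_motors < 0) stop("n_motors must be >= 0")
  if (atp_uM < 0) stop("atp_uM must be >= 0")
  if (dt > 1 / (2 * sample_hz))
    stop("dt must be <= 1/(2*sample_hz)")
  structure(list(k_trap = k_trap, gamma = gamma, dt = dt,
                 sample_hz = sample_hz, duration_s = duration_s,
                 n_motors = as.integer(n_motors), atp_uM = atp_uM, pca = pca,
                 anchor_spacing_nm = anchor_spacing_nm, seed = seed),
            class = "trap_config")
}

#' Base attachment rate ladder in the trap
#'
#' Fluctuations in the dumbbell height slow the first attachment to
#' 2.2 s^-1; a bound head damps those fluctuations, so the second head
#' attaches at an intermediate 36 s^-1 and subsequent heads at the solution
#' weak-to-strong rate of 40 s^-1.
#'
#' @param n_bound Number of currently strongly bound heads.
#' @param p A [motor_params()] object.
#' @return Base attachment rate, s^-1.
#' @export
attachment_rate_base <- function(n_bound, p = motor_params()) {
  if (!is.numeric(n_bound) || any(n_bound < 0))
    stop("n_bound must be >= 0")
  ifelse(n_bound == 0, p$k_a_single,
         ifelse(n_bound == 1, p$k_a2, p$k_ws))
}

#' Simulate a laser-trap displacement trace
#'
#' Hybrid Brownian/kinetic simulation: between kinetic transitions the bead
#' coordinate is an Ornstein-Uhlenbeck process (trap spring plus attached
#' motor springs, thermal noise at equipartition), discretised exactly;
#' kinetic transitions are evaluated every step with probability rate*dt.
#' Per-motor attachment rate is `attachment_rate_base(n_bound) *
#' activation_factor(...)`. The returned trace is downsampled to
#' `sample_hz` and carries the full configuration plus the ground-truth
#' strong-binding intervals as attributes.
#'
#' @param cfg A [trap_config()].
#' @param reg A [regulation_params()] object.
#' @param mp A [motor_params()] object.
#' @return A data frame of class `trap_trace` with columns `t_s`, `x_nm`,
#'   `f_pN` and attributes `meta` (configuration) and `truth` (true binding
#'   intervals).
#' @export
simulate_trace <- function(cfg = trap_config(), reg = regulation_params(),
                           mp = motor_params()) {
  stopifnot(inherits(cfg, "trap_config"), inherits(reg, "regulation_params"),
            inherits(mp, "motor_params"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_motors
  anchors <- if (n > 0) (seq_len(n) - (n + 1) / 2) * cfg$anchor_spacing_nm
             else numeric(0)
  eps <- epsilon_ca(pca_to_conc(cfg$pca), reg)
  sample_every <- max(1L, as.integer(round(1 / (cfg$sample_hz * cfg$dt))))
  res <- cpp_trap_simulate(anchors, cfg$k_trap, cfg$gamma, cfg$dt,
                           cfg$duration_s, sample_every, cfg$atp_uM, eps,
                           reg$partial_exponent, reg$ell_nm, mp$k_a_single,
                           mp$k_a2, mp$k_ws, mp$k_m, mp$d_stroke, mp$k_D0,
                           mp$delta_nm, mp$kBT, mp$k_T)
  fs <- 1 / (sample_every * cfg$dt)
  x <- res$x
  tr <- data.frame(t_s = seq_along(x) / fs, x_nm = x, f_pN = cfg$k_trap * x)
  attr(tr, "meta") <- list(cfg = cfg, reg = reg, mp = mp, eps = eps,
                           sample_hz_actual = fs)
  attr(tr, "truth") <- res$truth
  class(tr) <- c("trap_trace", "data.frame")
  tr
}

#' @export
print.trap_trace <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf(
    "Laser-trap trace: %.3g s at %g Hz, k_trap = %g pN/nm, %d motor(s)\n",
    nrow(x) / meta$sample_hz_actual, meta$sample_hz_actual,
    meta$cfg$k_trap, meta$cfg$n_motors))
  cat(sprintf("  pCa %g, ATP %g uM, eps = %.4g; %d true binding interval(s)\n",
              meta$cfg$pca, meta$cfg$atp_uM, meta$eps,
              nrow(attr(x, "truth"))))
  invisible(x)
}

#' Single-molecule binding frequency at a given calcium level
#'
#' Simulates single-molecule trap records and scores them with an event
#' detector until a target number of events (or a maximum simulated time) is
#' reached. Dividing the returned frequency by the unregulated single-
#' molecule frequency (`mp$k_a_single`, 2.2 s^-1) estimates the relative
#' attachment rate \eqn{\varepsilon}, independent of the effective actin
#' concentration in the assay.
#'
#' @param pca Calcium level as pCa.
#' @param reg,mp Model parameter objects.
#' @param n_events_target Stop once this many events are detected
#'   (default 50).
#' @param max_time_s Maximum total simulated time, s (default 600).
#' @param chunk_s Length of each simulated record, s (default 30).
#' @param cfg Template [trap_config()]; `n_motors`, `pca` and `duration_s`
#'   are overridden. The default uses 1 uM ATP so that strong-binding events
#'   are long-lived and detection losses are negligible.
#' @param dp [detection_params()] passed to the detector.
#' @param detector Which detector scores the records (default `"page"`).
#' @param seed Optional seed.
#' @return List with elements `frequency_hz` (events per second of record,
#'   the quantity the experiment reports), `attach_rate_hz` (events per
#'   second of *detached* time, the occupancy-corrected attachment rate),
#'   `se_hz`, `n_events`, `total_time_s`, `relative`
#'   (`attach_rate_hz / k_a_single`, the estimate of \eqn{\varepsilon}) and
#'   `upper_bound` (TRUE when no event was seen, in which case
#'   `frequency_hz` is the one-event upper bound, not a point estimate).
#' @export
single_molecule_frequency <- function(pca, reg = regulation_params(),
                                      mp = motor_params(),
                                      n_events_target = 50, max_time_s = 600,
                                      chunk_s = 30,
                                      cfg = trap_config(atp_uM = 1),
                                      dp = detection_params(),
                                      detector = c("page", "threshold",
                                                   "vardrop"),
                                      seed = NULL) {
  detector <- match.arg(detector)
  if (n_events_target < 1) stop("n_events_target must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cfg$n_motors <- 1L
  cfg$pca <- pca
  cfg$duration_s <- chunk_s
  cfg$seed <- NULL
  total_t <- 0
  bound_t <- 0
  n_ev <- 0
  while (n_ev < n_events_target && total_t < max_time_s) {
    tr <- simulate_trace(cfg, reg, mp)
    ev <- switch(detector,
                 page = detect_page(tr, dp),
                 threshold = detect_threshold(tr, dp),
                 vardrop = detect_variance_drop(tr, dp))
    n_ev <- n_ev + nrow(ev)
    bound_t <- bound_t + sum(ev$duration_ms) / 1000
    total_t <- total_t + chunk_s
  }
  if (n_ev == 0) {
    return(list(frequency_hz = 1 / total_t, attach_rate_hz = NA_real_,
                se_hz = NA_real_, n_events = 0L, total_time_s = total_t,
                relative = NA_real_, upper_bound = TRUE))
  }
  freq <- n_ev / total_t
  detached_t <- max(total_t - bound_t, total_t * 0.01)
  attach <- n_ev / detached_t
  list(frequency_hz = freq, attach_rate_hz = attach,
       se_hz = sqrt(n_ev) / total_t, n_events = as.integer(n_ev),
       total_time_s = total_t, relative = attach / mp$k_a_single,
       upper_bound = FALSE)
}
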
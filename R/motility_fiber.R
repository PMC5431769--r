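#' Motility assay configuration
#'
#' @param n_mot Number of heads able to interact with the filament
#'   (default 75).
#' @param filament_len_um Filament length, um (default 1).
#' @param spacing_nm Inter-motor anchor spacing along the filament axis, nm
#'   (default `1000 * filament_len_um / n_mot`).
#' @param atp_uM ATP concentration, uM.
#' @param pca Calcium level as pCa.
#' @param duration_s Simulated time per replicate, s (default 5).
#' @param min_len_um Filament length filter, um (default 0.5): shorter
#'   filaments are eliminated from curve averages.
#' @param stationary_cutoff_um_s Speed below which a filament is considered
#'   stationary, um/s (default 0.13).
#' @param include_stationary Include stationary replicates in mean speeds
#'   (default FALSE; they are reported as a stationary fraction either way).
#' @param seed Optional RNG seed.
#' @return An object of class `motility_config`.
#' @export
motility_config <- function(n_mot = 75, filament_len_um = 1,
                            spacing_nm = 1000 * filament_len_um / n_mot,
                            atp_uM = 100, pca = 9, duration_s = 5,
                            min_len_um = 0.5, stationary_cutoff_um_s = 0.13,
                            include_stationary = FALSE, seed = NULL) {
  if (n_mot < 1) stop("n_mot must be >= 1")
  if (spacing_nm <= 0) stop("spacing_nm must be > 0")
  if (min_len_um < 0 || stationary_cutoff_um_s < 0)
    stop("filters must be >= 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  structure(list(n_mot = as.integer(n_mot),
                 filament_len_um = filament_len_um, spacing_nm = spacing_nm,
                 atp_uM = atp_uM, pca = pca, duration_s = duration_s,
                 min_len_um = min_len_um,
                 stationary_cutoff_um_s = stationary_cutoff_um_s,
                 include_stationary = isTRUE(include_stationary),
                 seed = seed),
            class = "motility_config")
}

#' Half-sarcomere (isometric fiber) configuration
#'
#' @param n_motors Number of heads in the half-sarcomere (default 300).
#' @param spacing_nm Anchor spacing, nm (default 1000/75, the motility-assay
#'   density).
#' @param atp_uM ATP concentration, uM (default 4000, physiological).
#' @param pca_grid Calcium levels for the force-pCa curve.
#' @param duration_s Simulated time per replicate, s (default 5).
#' @param replicates Replicates per calcium level (default 3).
#' @param transient_frac Initial fraction of each run discarded before time
#'   averaging (default 0.1).
#' @param seed Optional RNG seed.
#' @return An object of class `fiber_config`.
#' @export
fiber_config <- function(n_motors = 300, spacing_nm = 1000 / 75,
                         atp_uM = 4000,
                         pca_grid = c(4, 5, 5.5, 6, 6.25, 6.5, 6.75, 7,
                                      7.25, 7.5, 8, 9),
                         duration_s = 5, replicates = 3,
                         transient_frac = 0.1, seed = NULL) {
  if (n_motors < 1) stop("n_motors must be >= 1")
  if (replicates < 1) stop("replicates must be >= 1")
  if (transient_frac < 0 || transient_frac >= 1)
    stop("transient_frac must be in [0, 1)")
  structure(list(n_motors = as.integer(n_motors), spacing_nm = spacing_nm,
                 atp_uM = atp_uM, pca_grid = pca_grid,
                 duration_s = duration_s,
                 replicates = as.integer(replicates),
                 transient_frac = transient_frac, seed = seed),
            class = "fiber_config")
}

#' Simulate filament transport in the motility assay
#'
#' Motors at fixed anchors attach at `k_ws * activation_factor(...)`; the
#' unloaded rigid filament sits quasi-statically at the zero-net-force
#' position of the attached motor springs, recomputed after every kinetic
#' transition, so the kinetics are simulated exactly (Gillespie).
#'
#' @param cfg A [motility_config()].
#' @param reg,mp Model parameter objects.
#' @param transient_frac Initial fraction of the run excluded from the
#'   speed (default 0.1): tracked filaments in the assay are already
#'   translocating, so the activation start-up from the all-detached
#'   initial state is not part of the measured speed.
#' @return List with `speed_um_s` (post-transient displacement / time),
#'   `stationary` (speed below the cutoff), `displacement_nm` (full-run net
#'   displacement), `n_events` and `mean_bound` (time-averaged strongly
#'   bound count).
#' @export
simulate_motility <- function(cfg = motility_config(),
                              reg = regulation_params(),
                              mp = motor_params(), transient_frac = 0.1) {
  stopifnot(inherits(cfg, "motility_config"),
            inherits(reg, "regulation_params"), inherits(mp, "motor_params"))
  if (transient_frac < 0 || transient_frac >= 1)
    stop("transient_frac must be in [0, 1)")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  eps <- epsilon_ca(pca_to_conc(cfg$pca), reg)
  res <- cpp_motility_simulate(cfg$n_mot, cfg$spacing_nm, cfg$duration_s,
                               cfg$atp_uM, eps, reg$partial_exponent,
                               reg$ell_nm, mp$k_ws, mp$k_m, mp$d_stroke,
                               mp$k_D0, mp$delta_nm, mp$kBT, mp$k_T,
                               FALSE, transient_frac)
  v <- abs(res$post_transient_nm) / 1000 /
    (cfg$duration_s * (1 - transient_frac))
  list(speed_um_s = v, stationary = v < cfg$stationary_cutoff_um_s,
       displacement_nm = res$displacement_nm, n_events = res$n_events,
       mean_bound = res$mean_bound)
}

#' Motility speed curves over calcium and ATP
#'
#' Runs replicate motility simulations on a (pCa, ATP) grid and applies the
#' published filters: simulated filaments shorter than `min_len_um` are
#' eliminated and replicates slower than `stationary_cutoff_um_s` are
#' counted as stationary (excluded from the mean speed unless
#' `include_stationary`).
#'
#' @param pca_list pCa values.
#' @param atp_list ATP concentrations, uM.
#' @param replicates Replicates per condition (>= 1).
#' @param cfg Template [motility_config()].
#' @param reg,mp Model parameter objects.
#' @param seed Optional seed for the whole grid.
#' @return Data frame of class `motility_curve`: one row per condition with
#'   `pca`, `atp_uM`, `mean_speed_um_s`, `sem_um_s`, `n` (replicates in the
#'   mean), `stationary_fraction`, `measurable` (FALSE when every replicate
#'   was filtered out; such conditions have `NA` mean, not 0).
#' @export
motility_curve <- function(pca_list, atp_list, replicates = 9,
                           cfg = motility_config(), reg = regulation_params(),
                           mp = motor_params(), seed = NULL) {
  if (replicates < 1) stop("need at least one replicate per condition")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(pca = pca_list, atp_uM = atp_list,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) {
    out <- data.frame(pca = numeric(0), atp_uM = numeric(0),
                      mean_speed_um_s = numeric(0), sem_um_s = numeric(0),
                      n = integer(0), stationary_fraction = numeric(0),
                      measurable = logical(0))
    class(out) <- c("motility_curve", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(grid)), function(ii) {
    cfg$pca <- grid$pca[ii]
    cfg$atp_uM <- grid$atp_uM[ii]
    cfg$seed <- NULL
    speeds <- vapply(seq_len(replicates), function(r)
      simulate_motility(cfg, reg, mp)$speed_um_s, numeric(1))
    summarise_speeds(speeds, grid$pca[ii], grid$atp_uM[ii], cfg)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("motility_curve", "data.frame")
  out
}

# shared by motility_curve and the filter-arithmetic API
summarise_speeds <- function(speeds, pca, atp_uM, cfg) {
  stationary <- speeds < cfg$stationary_cutoff_um_s
  keep <- if (cfg$include_stationary) rep(TRUE, length(speeds)) else !stationary
  n <- sum(keep)
  data.frame(
    pca = pca, atp_uM = atp_uM,
    mean_speed_um_s = if (n > 0) mean(speeds[keep]) else NA_real_,
    sem_um_s = if (n > 1) sd(speeds[keep]) / sqrt(n) else NA_real_,
    n = as.integer(n),
    stationary_fraction = mean(stationary),
    measurable = n > 0)
}

#' Apply the motility filters to replicate measurements
#'
#' Filter arithmetic used on both measured and simulated filaments:
#' filaments shorter than the length cutoff are eliminated, and speeds below
#' the stationary cutoff are excluded from the mean (but reported as a
#' stationary fraction).
#'
#' @param speeds_um_s Replicate speeds, um/s.
#' @param lengths_um Filament lengths, um (default: all long enough).
#' @param cfg A [motility_config()] carrying the cutoffs.
#' @param pca,atp_uM Condition labels attached to the output row.
#' @return One-row data frame as in [motility_curve()].
#' @export
filter_speeds <- function(speeds_um_s, lengths_um = NULL,
                          cfg = motility_config(), pca = NA_real_,
                          atp_uM = NA_real_) {
  if (!is.null(lengths_um)) {
    if (length(lengths_um) != length(speeds_um_s))
      stop("speeds and lengths lengths differ")
    speeds_um_s <- speeds_um_s[lengths_um >= cfg$min_len_um]
  }
  summarise_speeds(speeds_um_s, pca, atp_uM, cfg)
}

#' Critical ATP concentration of a biphasic motility curve
#'
#' At low calcium, filament speed rises linearly with ATP while rigor
#' lifetimes are long enough to keep the filament activated by strong
#' binding, then collapses above a critical ATP concentration. This returns
#' the ATP at maximal mean speed, refined parabolically around the grid
#' argmax. A curve whose maximum lies on the grid boundary has no interior
#' breakpoint and yields `NA` with a warning.
#'
#' @param curve A [motility_curve()] data frame.
#' @param pca Which pCa to analyse.
#' @return Critical ATP in uM, or `NA` if the curve is monotone.
#' @export
critical_atp <- function(curve, pca) {
  cc <- curve[curve$pca == pca & curve$measurable, , drop = FALSE]
  cc <- cc[order(cc$atp_uM), , drop = FALSE]
  if (nrow(cc) < 4)
    stop("need >= 4 measurable ATP points at this pCa")
  i <- which.max(cc$mean_speed_um_s)
  if (i == 1 || i == nrow(cc)) {
    warning("speed-ATP curve is monotone at pCa ", pca,
            ": no interior breakpoint")
    return(NA_real_)
  }
  # parabolic refinement in log(ATP) around the grid argmax
  la <- log(cc$atp_uM[(i - 1):(i + 1)])
  y <- cc$mean_speed_um_s[(i - 1):(i + 1)]
  denom <- (la[1] - la[2]) * (la[1] - la[3]) * (la[2] - la[3])
  if (abs(denom) < .Machine$double.eps) return(cc$atp_uM[i])
  a <- (la[3] * (y[2] - y[1]) + la[2] * (y[1] - y[3]) +
          la[1] * (y[3] - y[2])) / denom
  b <- (la[3]^2 * (y[1] - y[2]) + la[2]^2 * (y[3] - y[1]) +
          la[1]^2 * (y[2] - y[3])) / denom
  if (a >= 0) return(cc$atp_uM[i])
  exp(pmin(pmax(-b / (2 * a), la[1]), la[3]))
}

#' Isometric force-pCa curve of a simulated half-sarcomere
#'
#' Holds the filament fixed and time-averages the total force borne by the
#' strongly bound motors at each calcium level, discarding the initial
#' transient. Forces are normalised to the saturating-calcium (lowest pCa)
#' value for Hill fitting.
#'
#' @param cfg A [fiber_config()].
#' @param reg,mp Model parameter objects.
#' @return Data frame of class `force_pca_curve` with `pca`, `force_pN`
#'   (mean over replicates), `sd_pN`, `force_norm`, `n`.
#' @export
simulate_fiber_force <- function(cfg = fiber_config(),
                                 reg = regulation_params(),
                                 mp = motor_params()) {
  stopifnot(inherits(cfg, "fiber_config"),
            inherits(reg, "regulation_params"), inherits(mp, "motor_params"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  rows <- lapply(cfg$pca_grid, function(pca) {
    eps <- epsilon_ca(pca_to_conc(pca), reg)
    f <- vapply(seq_len(cfg$replicates), function(r) {
      res <- cpp_motility_simulate(cfg$n_motors, cfg$spacing_nm,
                                   cfg$duration_s, cfg$atp_uM, eps,
                                   reg$partial_exponent, reg$ell_nm,
                                   mp$k_ws, mp$k_m, mp$d_stroke, mp$k_D0,
                                   mp$delta_nm, mp$kBT, mp$k_T, TRUE,
                                   cfg$transient_frac)
      res$mean_force_pN
    }, numeric(1))
    data.frame(pca = pca, force_pN = mean(f),
               sd_pN = if (length(f) > 1) sd(f) else NA_real_,
               n = length(f))
  })
  out <- do.call(rbind, rows)
  anchor <- out$force_pN[which.min(out$pca)]
  out$force_norm <- out$force_pN / anchor
  class(out) <- c("force_pca_curve", "data.frame")
  out
}
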
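#' Crossbridge cycle parameters
#'
#' Rate and mechanical constants of the four-state actomyosin cycle
#' (detached, weakly bound, strongly bound with ADP, rigor). The weak state
#' is lumped into an effective attachment step; the base attachment rate is
#' supplied by the geometry (the trap ladder 2.2/36/40 s^-1, or the solution
#' weak-to-strong rate 40 s^-1 on a motility surface).
#'
#' @param k_ws Weak-to-strong transition rate in solution, s^-1 (default 40).
#' @param k_a_single Geometry-limited single-molecule attachment rate in the
#'   trap, s^-1 (default 2.2).
#' @param k_a2 Attachment rate of the second motor in the trap, s^-1
#'   (default 36).
#' @param k_T Second-order rate constant of ATP-induced rigor detachment,
#'   per uM per s (default 3).
#' @param d_stroke Powerstroke displacement, nm (default 10).
#' @param k_m Motor stiffness, pN/nm (default 0.3).
#' @param k_D0 Unloaded ADP release rate, s^-1 (default 500; sets the
#'   detachment-limited unloaded gliding speed `d_stroke * k_D0` to about
#'   5 um/s, typical of fast skeletal myosin at 30 C).
#' @param delta_nm Bell force-sensitivity distance for ADP release, nm
#'   (default 1.0).
#' @param kBT Thermal energy, pN nm (default 4.14, 30 C).
#' @return An object of class `motor_params`.
#' @export
motor_params <- function(k_ws = 40, k_a_single = 2.2, k_a2 = 36, k_T = 3,
                         d_stroke = 10, k_m = 0.3, k_D0 = 500,
                         delta_nm = 1.0, kBT = 4.14) {
  vals <- c(k_ws = k_ws, k_a_single = k_a_single, k_a2 = k_a2, k_T = k_T,
            d_stroke = d_stroke, k_m = k_m, k_D0 = k_D0,
            delta_nm = delta_nm, kBT = kBT)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all motor parameters must be finite and >= 0")
  if (!(k_a_single <= k_a2 && k_a2 <= k_ws))
    stop("need k_a_single <= k_a2 <= k_ws (attachment-rate ladder)")
  if (kBT <= 0) stop("kBT must be > 0")
  structure(as.list(vals), class = "motor_params")
}

#' @export
print.motor_params <- function(x, ...) {
  cat("Crossbridge parameters\n")
  cat(sprintf("  attachment ladder: %g / %g / %g s^-1\n",
              x$k_a_single, x$k_a2, x$k_ws))
  cat(sprintf("  k_T = %g uM^-1 s^-1, k_D0 = %g s^-1, delta = %g nm\n",
              x$k_T, x$k_D0, x$delta_nm))
  cat(sprintf("  d_stroke = %g nm, k_m = %g pN/nm, kBT = %g pN nm\n",
              x$d_stroke, x$k_m, x$kBT))
  invisible(x)
}

#' A single myosin motor
#'
#' @param anchor_nm Fixed anchor coordinate along the filament axis (nm).
#' @param state One of `"DETACHED"`, `"WEAK"`, `"STRONG_ADP"`, `"RIGOR"`.
#' @param attach_site_nm Filament coordinate the head is bound to (nm);
#'   must be given iff the motor is attached.
#' @param stroked Whether the powerstroke displacement has been applied.
#' @return An object of class `motor_instance`.
#' @export
motor_instance <- function(anchor_nm, state = "DETACHED",
                           attach_site_nm = NA_real_, stroked = FALSE) {
  state <- match.arg(state, c("DETACHED", "WEAK", "STRONG_ADP", "RIGOR"))
  attached <- state %in% c("WEAK", "STRONG_ADP", "RIGOR")
  if (attached && !is.finite(attach_site_nm))
    stop("attached motor needs a finite attach_site_nm")
  if (!attached && is.finite(attach_site_nm))
    stop("detached motor must not have an attach site")
  structure(list(anchor_nm = anchor_nm, state = state,
                 attach_site_nm = attach_site_nm, stroked = isTRUE(stroked)),
            class = "motor_instance")
}

#' Elastic force borne by an attached motor
#'
#' The motor link is a linear spring: the force is `k_m` times the extension
#' `(x_filament + attach_site + stroke) - anchor`. Positive force resists
#' filament motion in the +x direction.
#'
#' @param m A [motor_instance()].
#' @param x_filament_nm Filament displacement (nm).
#' @param p A [motor_params()] object.
#' @return Force in pN.
#' @export
motor_force <- function(m, x_filament_nm, p = motor_params()) {
  stopifnot(inherits(m, "motor_instance"), inherits(p, "motor_params"))
  if (m$state == "DETACHED")
    stop("motor_force called on a detached motor")
  ext <- x_filament_nm + m$attach_site_nm +
    (if (m$stroked) p$d_stroke else 0) - m$anchor_nm
  p$k_m * ext
}

#' Load-dependent ADP release rate (Bell equation)
#'
#' `k_D0 * exp(-force * delta / kBT)`, clamped to `[0, k_D0 * exp(5)]`.
#' Positive (resisting) load slows ADP release; assisting load accelerates it.
#'
#' @param force_pN Load on the motor, pN (positive resists the powerstroke).
#' @param p A [motor_params()] object.
#' @return Rate in s^-1.
#' @export
k_adp <- function(force_pN, p = motor_params()) {
  stopifnot(inherits(p, "motor_params"))
  r <- p$k_D0 * exp(-force_pN * p$delta_nm / p$kBT)
  pmin(pmax(r, 0), p$k_D0 * exp(5))
}

#' Kinetic transition rates of a motor
#'
#' Returns the rate of each transition allowed from the motor's current
#' state. Attachment (detached -> strongly bound, the weak state lumped in)
#' proceeds at `base_attach_rate * attach_multiplier`, where the base rate is
#' set by the assay geometry and the multiplier by thin-filament regulation.
#' Strongly bound (ADP) motors release ADP at the load-dependent rate
#' [k_adp()]; rigor motors detach at `k_T * [ATP]`.
#'
#' @param m A [motor_instance()].
#' @param force_pN Load on the motor, pN.
#' @param atp_uM ATP concentration, uM (>= 0).
#' @param attach_multiplier Regulation multiplier in `(0, 1]`.
#' @param p A [motor_params()] object.
#' @param base_attach_rate Geometry-set base attachment rate, s^-1
#'   (default `p$k_ws`).
#' @return Named numeric vector of rates (s^-1).
#' @export
transition_rates <- function(m, force_pN = 0, atp_uM = 100,
                             attach_multiplier = 1, p = motor_params(),
                             base_attach_rate = p$k_ws) {
  stopifnot(inherits(m, "motor_instance"), inherits(p, "motor_params"))
  if (!is.finite(atp_uM) || atp_uM < 0) stop("atp_uM must be >= 0")
  if (!is.finite(attach_multiplier) || attach_multiplier <= 0 ||
      attach_multiplier > 1)
    stop("attach_multiplier must be in (0, 1]")
  switch(m$state,
    DETACHED = c(attach = base_attach_rate * attach_multiplier),
    WEAK = c(attach = base_attach_rate * attach_multiplier),
    STRONG_ADP = c(adp_release = unname(k_adp(force_pN, p))),
    RIGOR = c(detach = p$k_T * atp_uM)
  )
}
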
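#' Thin-filament regulation parameters
#'
#' Parameters of the two-parameter regulation model: the calcium-dependent
#' relative weak-to-strong attachment rate \eqn{\varepsilon} interpolates
#' geometrically between `eps_min` (no calcium) and `eps_max` (saturating
#' calcium) through the troponin saturation \eqn{\theta}, and a strongly
#' bound myosin locally activates the filament over the coupling distance
#' `ell_nm` on either side.
#'
#' @param eps_min Relative attachment rate in the absence of calcium
#'   (dimensionless, default 0.006).
#' @param eps_max Relative attachment rate at saturating calcium (default 0.5).
#' @param K_uM Michaelis constant of troponin C for calcium, in uM
#'   (default 0.2).
#' @param ell_nm Coupling distance along the filament axis, in nm
#'   (default 400).
#' @param partial_exponent Exponent applied to \eqn{\varepsilon} when a
#'   detached motor has a strongly bound neighbour within `ell_nm` on exactly
#'   one side (default 0.5, the geometric mean of \eqn{\varepsilon} and full
#'   activation).
#' @return An object of class `regulation_params`.
#' @export
regulation_params <- function(eps_min = 0.006, eps_max = 0.5, K_uM = 0.2,
                              ell_nm = 400, partial_exponent = 0.5) {
  stopifnot(is.numeric(eps_min), is.numeric(eps_max), is.numeric(K_uM),
            is.numeric(ell_nm), is.numeric(partial_exponent))
  if (!(eps_min > 0 && eps_min <= eps_max && eps_max <= 1))
    stop("need 0 < eps_min <= eps_max <= 1")
  if (K_uM <= 0) stop("K_uM must be > 0")
  if (ell_nm < 0) stop("ell_nm must be >= 0")
  if (partial_exponent < 0 || partial_exponent > 1)
    stop("partial_exponent must be in [0, 1]")
  structure(list(eps_min = eps_min, eps_max = eps_max, K_uM = K_uM,
                 ell_nm = ell_nm, partial_exponent = partial_exponent),
            class = "regulation_params")
}

#' @export
print.regulation_params <- function(x, ...) {
  cat("Thin-filament regulation parameters\n")
  cat(sprintf("  eps_min = %g, eps_max = %g\n", x$eps_min, x$eps_max))
  cat(sprintf("  K = %g uM, ell = %g nm, partial exponent = %g\n",
              x$K_uM, x$ell_nm, x$partial_exponent))
  invisible(x)
}

#' Convert between pCa and calcium concentration
#'
#' pCa is the negative decadic logarithm of the molar calcium concentration;
#' concentrations are expressed in uM, so `conc_uM = 10^(6 - pca)`.
#'
#' @param pca pCa value(s).
#' @return Calcium concentration in uM.
#' @examples
#' pca_to_conc(6) # 1 uM
#' @export
pca_to_conc <- function(pca) {
  if (!is.numeric(pca) || any(!is.finite(pca)))
    stop("pca must be finite numeric")
  10^(6 - pca)
}

#' @rdname pca_to_conc
#' @param conc_uM Calcium concentration(s) in uM.
#' @export
conc_to_pca <- function(conc_uM) {
  if (!is.numeric(conc_uM) || any(!is.finite(conc_uM)) || any(conc_uM <= 0))
    stop("conc_uM must be finite and positive")
  6 - log10(conc_uM)
}

#' Fraction of troponin with bound calcium
#'
#' Michaelis-Menten saturation of troponin C with calcium:
#' \eqn{\theta = [Ca]/(K + [Ca])}.
#'
#' @param conc_uM Calcium concentration in uM (>= 0).
#' @param K_uM Michaelis constant in uM (> 0).
#' @return Saturation fraction in `[0, 1)`.
#' @export
theta_ca <- function(conc_uM, K_uM) {
  if (!is.numeric(conc_uM) || any(!is.finite(conc_uM)) || any(conc_uM < 0))
    stop("conc_uM must be finite and >= 0")
  if (!is.numeric(K_uM) || any(K_uM <= 0)) stop("K_uM must be > 0")
  conc_uM / (K_uM + conc_uM)
}

#' Relative single-molecule attachment rate as a function of calcium
#'
#' \eqn{\varepsilon = \varepsilon_{min}^{1-\theta}\,\varepsilon_{max}^{\theta}}:
#' the energy barrier the regulatory proteins impose on the weak-to-strong
#' transition interpolates linearly in the troponin saturation \eqn{\theta},
#' so the rate interpolates geometrically between its calcium-free and
#' calcium-saturated values.
#'
#' @param conc_uM Calcium concentration in uM.
#' @param params A [regulation_params()] object.
#' @return Relative rate in `[eps_min, eps_max]`.
#' @export
epsilon_ca <- function(conc_uM, params = regulation_params()) {
  stopifnot(inherits(params, "regulation_params"))
  th <- theta_ca(conc_uM, params$K_uM)
  exp((1 - th) * log(params$eps_min) + th * log(params$eps_max))
}

#' Local activation multiplier for a detached motor
#'
#' Counts strongly bound motors within the coupling distance of motor `i` on
#' each side along the filament axis. With none, the motor attaches at the
#' calcium-set relative rate `eps`; flanked on both sides the intervening
#' filament is fully activated (multiplier 1); with a bound neighbour on
#' exactly one side the filament is partially activated and the multiplier is
#' `eps^partial_exponent`.
#'
#' @param positions_nm Motor anchor coordinates along the filament axis,
#'   sorted ascending (nm).
#' @param bound Logical vector: which motors are strongly bound.
#' @param i Index of the (detached) motor being evaluated.
#' @param eps Relative attachment rate at the current calcium level.
#' @param params A [regulation_params()] object (supplies `ell_nm` and
#'   `partial_exponent`).
#' @return Multiplier in `[eps, 1]`.
#' @export
activation_factor <- function(positions_nm, bound, i, eps,
                              params = regulation_params()) {
  stopifnot(inherits(params, "regulation_params"))
  n <- length(positions_nm)
  if (length(bound) != n) stop("positions_nm and bound lengths differ")
  if (!is.numeric(i) || length(i) != 1 || i < 1 || i > n)
    stop("motor index i out of range")
  if (is.unsorted(positions_nm)) stop("positions_nm must be sorted ascending")
  if (isTRUE(bound[i])) stop("motor i must not be strongly bound")
  ell <- params$ell_nm
  if (ell <= 0) return(eps)
  dx <- positions_nm - positions_nm[i]
  near <- bound & abs(dx) < ell & seq_len(n) != i
  has_left <- any(near & dx < 0)
  has_right <- any(near & dx > 0)
  if (has_left && has_right) 1
  else if (has_left || has_right) eps^params$partial_exponent
  else eps
}
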
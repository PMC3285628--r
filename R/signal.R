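#' Receptor stimulation schedules
#'
#' A signal schedule maps (position, time) to the activated-receptor
#' surface density `rho_R(x, t)` (molecules/um^2) that recruits the
#' activating enzyme to the membrane.  Supported forms:
#'
#' * `"constant"` - `rho_R` at all times.
#' * `"step"` - 0 before `t_on`, `rho_R` afterwards.
#' * `"adapting"` - 0 before `t_on`; afterwards an exponential decay from
#'   the full amplitude towards a plateau,
#'   `rho_R * (plateau + (1 - plateau) * exp(-(t - t_on)/tau))`.
#'   This imposes receptor-level adaptation with timescale `tau`; the
#'   adaptation mechanism itself is upstream of this model and is not
#'   resolved.
#' * `"gradient"` - static spatial profile
#'   `rho_R * (1 + cos(theta)) / 2` where `theta` is the polar angle from
#'   `axis`, optionally gated by `t_on`.
#'
#' @param type one of `"constant"`, `"step"`, `"adapting"`, `"gradient"`.
#' @param rho_R peak activated-receptor density (molecules/um^2).
#' @param t_on switch-on time (s).
#' @param tau adaptation timescale (s), for `"adapting"`.
#' @param plateau residual fraction of the amplitude after adaptation.
#' @param axis length-3 vector, gradient axis for `"gradient"`.
#' @return an object of class `signal_schedule`.
#' @examples
#' s <- signal_schedule("adapting", rho_R = 300, tau = 15, plateau = 0.05)
#' receptor_density(s, t = c(0, 15, 150))
#' @export
signal_schedule <- function(type = c("constant", "step", "adapting", "gradient"),
                            rho_R = 0, t_on = 0, tau = NULL, plateau = 0,
                            axis = c(0, 0, 1)) {
  type <- match.arg(type)
  if (rho_R < 0) stop("rho_R must be nonnegative")
  if (type == "adapting") {
    if (is.null(tau) || tau <= 0) stop("adapting schedule needs tau > 0")
    if (plateau < 0 || plateau > 1) stop("plateau must be in [0, 1]")
  }
  if (type == "gradient") {
    axis <- as.numeric(axis)
    if (length(axis) != 3 || sum(axis^2) == 0) stop("axis must be a nonzero 3-vector")
    axis <- axis / sqrt(sum(axis^2))
  }
  structure(list(type = type, rho_R = rho_R, t_on = t_on, tau = tau,
                 plateau = plateau, axis = axis),
            class = "signal_schedule")
}

#' @export
format.signal_schedule <- function(x, ...) {
  switch(x$type,
         constant = sprintf("constant rho_R = %g /um^2", x$rho_R),
         step = sprintf("step to rho_R = %g /um^2 at t = %g s", x$rho_R, x$t_on),
         adapting = sprintf("step to %g /um^2 at t = %g s, adapting (tau = %g s) to %g%%",
                            x$rho_R, x$t_on, x$tau, 100 * x$plateau),
         gradient = sprintf("cosine gradient, peak rho_R = %g /um^2", x$rho_R))
}

#' @export
print.signal_schedule <- function(x, ...) {
  cat("signal schedule:", format(x), "\n")
  invisible(x)
}

#' Evaluate a signal schedule
#'
#' @param signal a [signal_schedule()].
#' @param t time (s); scalar or vector (vector only with `points = NULL`).
#' @param points optional n-by-3 matrix of membrane positions; required for
#'   spatially varying schedules, ignored otherwise.
#' @return the activated-receptor density: a scalar (or vector over `t`)
#'   for uniform schedules, or a vector over rows of `points` for a
#'   gradient schedule at a single time.
#' @export
receptor_density <- function(signal, t, points = NULL) {
  stopifnot(inherits(signal, "signal_schedule"))
  amp <- switch(signal$type,
    constant = rep(signal$rho_R, length(t)),
    step = ifelse(t >= signal$t_on, signal$rho_R, 0),
    adapting = ifelse(t >= signal$t_on,
                      signal$rho_R * (signal$plateau + (1 - signal$plateau) *
                                        exp(-(t - signal$t_on) / signal$tau)),
                      0),
    gradient = ifelse(t >= signal$t_on, signal$rho_R, 0))
  if (signal$type == "gradient") {
    if (is.null(points)) stop("gradient schedule needs membrane positions")
    if (length(t) != 1) stop("gradient schedule: one time at a time")
    u <- points %*% signal$axis / sqrt(rowSums(points^2))
    return(as.numeric(amp * (1 + u) / 2))
  }
  if (!is.null(points)) return(rep(amp[1], nrow(points)))
  amp
}

#' Renormalized activation signal for a given receptor density
#'
#' Converts an activated-receptor density into the dimensionless
#' renormalized signal `sigma = ktil_R * rho_R / (ktil_X * X_tot)`, i.e.
#' receptor-driven enzyme recruitment measured in units of the
#' feedback-driven recruitment at full activation (`ktil = k_on / k_off`).
#'
#' @param rho_R activated-receptor density (molecules/um^2).
#' @param params a [polarity_params()] object.
#' @return `sigma`, dimensionless (vectorized over `rho_R`).
#' @export
sigma_from_receptor <- function(rho_R, params) {
  kx <- ktil_X(params)
  if (kx <= 0) stop("sigma is undefined when the A <- X* feedback loop is absent (k_on_X = 0)")
  ktil_R(params) * rho_R / (kx * params$X_tot)
}

#' @rdname sigma_from_receptor
#' @param sigma renormalized signal to invert.
#' @export
receptor_from_sigma <- function(sigma, params) {
  kr <- ktil_R(params)
  if (kr <= 0) stop("no receptor coupling (k_on_R = 0)")
  sigma * ktil_X(params) * params$X_tot / kr
}
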
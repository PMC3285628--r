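#' Net enzymatic conversion flux
#'
#' The Michaelis-Menten interconversion term of the mean-field dynamics:
#' the net rate of `X0 -> X*` conversion per unit membrane area,
#' \deqn{F = k_{catA} (a_R + a_X) \frac{x_0}{K_A + x_0}
#'         - k_{catB} b \frac{x^*}{K_B + x^*}.}
#' There is no basal (enzyme-independent) interconversion.
#'
#' @param x_star,x_0 surface densities of the activated/unactivated
#'   signaling species (molecules/um^2); vectors of common length.
#' @param a_R,a_X,b surface densities of receptor-recruited A,
#'   feedback-recruited A, and bound B (molecules/um^2).
#' @param params a [polarity_params()] object.
#' @return the net conversion flux (molecules/um^2/s), vectorized.
#' @examples
#' p <- polarity_params()
#' conversion_flux(300, 300, 0, 0, 0, p)  # no enzyme, no flux
#' @export
conversion_flux <- function(x_star, x_0, a_R, a_X, b, params) {
  if (any(c(x_star, x_0, a_R, a_X, b) < 0))
    stop("conversion_flux: negative density")
  params$k_cat_A * (a_R + a_X) * x_0 / (params$K_A + x_0) -
    params$k_cat_B * b * x_star / (params$K_B + x_star)
}

#' Quasi-steady-state enzyme distribution slaved to the slow fields
#'
#' At the enzyme-shuttling equilibrium the bound-enzyme densities are
#' proportional to their recruiters,
#' `a_R = ktil_R * rho_R * A_cyt/V_cyt`,
#' `a_X = ktil_X * x* * A_cyt/V_cyt`,
#' `b = ktil_B * x0 * B_cyt/V_cyt` (`ktil = k_on/k_off`, units um^3),
#' with the free reservoir counts `A_cyt`, `B_cyt` fixed self-consistently
#' by enzyme conservation.  Because recruitment is linear in the free
#' cytosolic concentration, the two conservation equations decouple and are
#' solved in closed form, so bound + free equals the total exactly.
#'
#' @param x_star,x_0 surface-density fields (molecules/um^2).
#' @param receptor activated-receptor density field (molecules/um^2);
#'   scalar or vector.
#' @param params a [polarity_params()] object.
#' @param weights quadrature weights (node areas, um^2) summing to
#'   `S_area`; defaults to a uniform partition.
#' @return list with fields `a_R`, `a_X`, `b` (same shape as `x_star`) and
#'   scalars `A_cyt`, `B_cyt` (free copy counts).
#' @export
enzyme_equilibria <- function(x_star, x_0, receptor, params,
                              weights = NULL) {
  n <- length(x_star)
  if (is.null(weights)) weights <- rep(params$S_area / n, n)
  # mesh quadratures underestimate the sphere area (inscribed triangles:
  # 24% on the raw icosahedron, <1% from subdivision level 3); the check
  # only guards against weights in the wrong units
  if (abs(sum(weights) - params$S_area) > 0.25 * params$S_area)
    stop("quadrature weights must sum to S_area")
  receptor <- rep_len(receptor, n)
  kR <- ktil_R(params); kX <- ktil_X(params); kB <- ktil_B(params)
  # conservation: A_cyt * (1 + (kR*Int(rho_R) + kX*Int(x*)) / V) = A_tot
  loadA <- (kR * sum(weights * receptor) + kX * sum(weights * x_star)) / params$V_cyt
  loadB <- kB * sum(weights * x_0) / params$V_cyt
  A_cyt <- params$A_tot / (1 + loadA)
  B_cyt <- params$B_tot / (1 + loadB)
  cA <- A_cyt / params$V_cyt
  cB <- B_cyt / params$V_cyt
  list(a_R = kR * receptor * cA,
       a_X = kX * x_star * cA,
       b = kB * x_0 * cB,
       A_cyt = A_cyt, B_cyt = B_cyt)
}

#' Reduced coordinates of the single-field dynamics
#'
#' Maps reservoir occupancies and the stimulation level to the two
#' coordinates that control the reduced dynamics: the enzyme ratio
#' \deqn{\rho = \frac{k_{catA}\, \tilde k_X\, c_A}{k_{catB}\, \tilde k_B\, c_B},}
#' measuring the relative strength of the activating versus deactivating
#' arm (A over B: large `rho` favours the activated phase), and the
#' renormalized activation signal
#' `sigma = ktil_R * rho_R / (ktil_X * X_tot)` (see
#' [sigma_from_receptor()]).  Also returns the deactivation rate scale
#' `gamma = k_cat_B * ktil_B * c_B * X_tot / X_tot` used to give the
#' reduced reaction term absolute units of 1/s.
#'
#' @param A_cyt,B_cyt free cytosolic enzyme copy counts.
#' @param rho_R activated-receptor density (molecules/um^2).
#' @param params a [polarity_params()] object.
#' @return list with `rho`, `sigma`, `gamma` (1/s).
#' @export
reduced_coordinates <- function(A_cyt, B_cyt, rho_R, params) {
  cA <- A_cyt / params$V_cyt
  cB <- B_cyt / params$V_cyt
  num <- params$k_cat_A * ktil_X(params) * cA
  den <- params$k_cat_B * ktil_B(params) * cB
  if (den <= 0) stop("enzyme ratio undefined: deactivating arm has zero strength")
  list(rho = num / den,
       sigma = sigma_from_receptor(rho_R, params),
       gamma = den)
}

#' Reduced reaction term f(phi)
#'
#' After the quasi-steady-state substitution of the bound-enzyme fields and
#' use of the pointwise conservation `x* + x0 = X_tot`, the local chemistry
#' collapses to a single activated fraction `phi = x*/X_tot` obeying
#' `dphi/dt = f(phi; rho, sigma)` with
#' \deqn{f(\phi) = \gamma (1-\phi)\left[
#'    \rho \frac{\sigma + \phi}{\kappa_A + 1 - \phi}
#'    - \frac{\phi}{\kappa_B + \phi}\right],}
#' where `kappa = K / X_tot` are the dimensionless Michaelis constants.
#' Zeros of `f` are the chemical equilibria.  `phi = 1` is always an
#' equilibrium: at full activation no `X0` remains to recruit the
#' deactivating enzyme, so both conversion arms vanish.
#'
#' @param phi activated fraction(s) in `[0, 1]`.
#' @param rho enzyme ratio, `> 0`.
#' @param sigma renormalized activation signal, `>= 0`.
#' @param params a [polarity_params()] object (supplies `kappa_A`,
#'   `kappa_B` and the default rate scale).
#' @param rate_scale overall rate `gamma` (1/s).  Defaults to the
#'   deactivation scale at the all-free reservoir reference,
#'   `k_cat_B * ktil_B * B_tot / V_cyt`.  Irrelevant for root finding and
#'   phase classification; it fixes absolute timescales only.
#' @return `f(phi)` in 1/s, vectorized over `phi`.
#' @export
reduced_reaction <- function(phi, rho, sigma, params, rate_scale = NULL) {
  if (!is.numeric(rho) || rho <= 0) stop("rho must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (any(phi < -1e-12 | phi > 1 + 1e-12)) stop("phi must lie in [0, 1]")
  phi <- pmin(pmax(phi, 0), 1)
  if (is.null(rate_scale))
    rate_scale <- params$k_cat_B * ktil_B(params) * params$B_tot / params$V_cyt
  kA <- kappa_A(params); kB <- kappa_B(params)
  rate_scale * (1 - phi) *
    (rho * (sigma + phi) / (kA + 1 - phi) - phi / (kB + phi))
}

#' Effective potential of the reduced dynamics
#'
#' \eqn{V(\phi) = -\int_0^\phi f(u)\,du}, normalized so that `V(0) = 0`.
#' The reduced dynamics descends this potential, which is a bookkeeping
#' device for the direction of the catalytic and diffusive fluxes - it does
#' not measure any consumed chemical energy.  Computed by adaptive
#' quadrature on each grid interval (absolute tolerance 1e-10).
#'
#' @param phi_grid strictly increasing grid in `[0, 1]`.
#' @param rho,sigma reduced coordinates.
#' @param params a [polarity_params()] object.
#' @param rate_scale optional rate scale passed to [reduced_reaction()].
#' @return data.frame with columns `phi` and `V` (V in 1/s, since phi is
#'   dimensionless).
#' @export
effective_potential <- function(phi_grid, rho, sigma, params,
                                rate_scale = NULL) {
  if (any(diff(phi_grid) <= 0)) stop("phi_grid must be strictly increasing")
  if (phi_grid[1] < 0 || tail(phi_grid, 1) > 1) stop("phi_grid must lie in [0, 1]")
  f <- function(u) reduced_reaction(u, rho, sigma, params, rate_scale)
  # integrate piecewise from 0 to each grid point
  lower <- c(0, head(phi_grid, -1))
  pieces <- vapply(seq_along(phi_grid), function(i) {
    if (phi_grid[i] == lower[i]) return(0)
    stats::integrate(f, lower[i], phi_grid[i], abs.tol = 1e-10,
                     rel.tol = 1e-10, subdivisions = 400L)$value
  }, numeric(1))
  data.frame(phi = phi_grid, V = -cumsum(pieces))
}

# V at specific points, with V(0) = 0 (internal; adaptive quadrature)
potential_at <- function(phi, rho, sigma, params, rate_scale = NULL) {
  f <- function(u) reduced_reaction(u, rho, sigma, params, rate_scale)
  vapply(phi, function(ph) {
    if (ph == 0) return(0)
    -stats::integrate(f, 0, ph, abs.tol = 1e-10, rel.tol = 1e-10,
                      subdivisions = 400L)$value
  }, numeric(1))
}

#' Spatially uniform mean-field dynamics
#'
#' Integrates the space-free version of the full mean-field system: the
#' five membrane species densities (`x*`, `x0`, `a_R`, `a_X`, `b`) and the
#' two reservoir counts, under a signal schedule.  Used to study the
#' uniform transient of a stimulation protocol and as the deterministic
#' reference for the stochastic engine.
#'
#' @param times output times (s), increasing.
#' @param params a [polarity_params()] object (its `signal` is used).
#' @param phi0 initial activated fraction; the initial bound-enzyme fields
#'   are set to their equilibria at `phi0` and the initial signal value.
#' @param state0 optional full initial state: named list with `x_star`,
#'   `x_0`, `a_R`, `a_X`, `b`, `A_cyt`, `B_cyt` (overrides `phi0`).
#' @param rtol,atol solver tolerances (lsoda).
#' @return data.frame over `times` with the seven state variables plus
#'   `phi`, `rho`, `sigma`.
#' @export
simulate_local <- function(times, params, phi0 = 0, state0 = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  sig <- params$signal
  if (!is.null(state0)) {
    y0 <- unlist(state0[c("x_star", "x_0", "a_R", "a_X", "b", "A_cyt", "B_cyt")])
  } else {
    rho_R0 <- receptor_density(sig, times[1])
    eq <- enzyme_equilibria(phi0 * params$X_tot, (1 - phi0) * params$X_tot,
                            rho_R0, params, weights = params$S_area)
    y0 <- c(x_star = phi0 * params$X_tot, x_0 = (1 - phi0) * params$X_tot,
            a_R = eq$a_R, a_X = eq$a_X, b = eq$b,
            A_cyt = eq$A_cyt, B_cyt = eq$B_cyt)
  }
  S <- params$S_area; V <- params$V_cyt
  rhs <- function(t, y, parms) {
    rho_R <- receptor_density(sig, t)
    cA <- y[["A_cyt"]] / V; cB <- y[["B_cyt"]] / V
    # clamp the solver's tiny negative excursions
    F <- conversion_flux(max(y[["x_star"]], 0), max(y[["x_0"]], 0),
                         max(y[["a_R"]], 0), max(y[["a_X"]], 0),
                         max(y[["b"]], 0), params)
    d_aR <- params$k_on_R * rho_R * cA - params$k_off_AR * y[["a_R"]]
    d_aX <- params$k_on_X * y[["x_star"]] * cA - params$k_off_AX * y[["a_X"]]
    d_b <- params$k_on_B * y[["x_0"]] * cB - params$k_off_B * y[["b"]]
    list(c(F, -F, d_aR, d_aX, d_b, -S * (d_aR + d_aX), -S * d_b))
  }
  out <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol, atol = atol)
  out <- as.data.frame(out)
  out$phi <- out$x_star / params$X_tot
  rc <- t(vapply(seq_len(nrow(out)), function(i) {
    r <- reduced_coordinates(out$A_cyt[i], out$B_cyt[i],
                             receptor_density(sig, out$time[i]), params)
    c(r$rho, r$sigma)
  }, numeric(2)))
  out$rho <- rc[, 1]; out$sigma <- rc[, 2]
  out
}
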
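#' Membrane state on a spherical mesh
#'
#' Builds a `membrane_state`: per-node surface densities of the five
#' membrane species plus the two cytosolic reservoir counts.  The
#' bound-enzyme fields are initialized at their shuttling equilibria for
#' the given lipid field and the signal evaluated at `time`, and the
#' reservoirs close the conservation laws exactly.
#'
#' @param mesh a [build_sphere_mesh()] object.
#' @param params a [polarity_params()] object.
#' @param phi initial activated fraction: scalar or per-node vector.
#' @param noise_rel optional multiplicative Gaussian roughness: each node's
#'   `x*` is scaled by `1 + noise_rel * z` with `z ~ N(0,1)` truncated at
#'   +/- 3, then clipped to `[0, X_tot]` (the complement goes to `x0`, so
#'   the pointwise total is preserved).  Uses the current RNG state.
#' @param germ optional circular germ: list with `center` (length-3
#'   direction or a node index), `radius` (geodesic radius, um) and
#'   `phi_in` (activated fraction inside the germ).
#' @param time initial time stamp (s).
#' @return an object of class `membrane_state` with fields `x_star`,
#'   `x_0`, `a_R`, `a_X`, `b` (vectors over nodes), `A_cyt`, `B_cyt`,
#'   `time`.
#' @export
initial_state <- function(mesh, params, phi = 0, noise_rel = 0,
                          germ = NULL, time = 0) {
  n <- nrow(mesh$vertices)
  phi <- rep_len(phi, n)
  if (!is.null(germ)) {
    ctr <- germ$center
    if (length(ctr) == 1L) ctr <- mesh$vertices[ctr, ]
    ctr <- ctr / sqrt(sum(ctr^2))
    cosd <- pmin(pmax((mesh$vertices %*% ctr) / mesh$R, -1), 1)
    inside <- mesh$R * acos(cosd) <= germ$radius
    phi[inside] <- germ$phi_in
  }
  if (noise_rel > 0) {
    z <- pmin(pmax(rnorm(n), -3), 3)
    phi <- phi * (1 + noise_rel * z)
  }
  phi <- pmin(pmax(phi, 0), 1)
  x_star <- phi * params$X_tot
  x_0 <- params$X_tot - x_star
  rec <- receptor_density(params$signal, time, mesh$vertices)
  eq <- enzyme_equilibria(x_star, x_0, rec, params, weights = mesh$areas)
  structure(list(x_star = x_star, x_0 = x_0, a_R = eq$a_R, a_X = eq$a_X,
                 b = eq$b, A_cyt = eq$A_cyt, B_cyt = eq$B_cyt,
                 time = time),
            class = "membrane_state")
}

#' @export
print.membrane_state <- function(x, ...) {
  cat(sprintf("membrane state at t = %.4g s: %d nodes, mean phi = %.4f, A_cyt = %.4g, B_cyt = %.4g\n",
              x$time, length(x$x_star),
              mean(x$x_star / (x$x_star + x$x_0)), x$A_cyt, x$B_cyt))
  invisible(x)
}

#' Right-hand side of the spatially distributed mean-field equations
#'
#' Time derivatives of every field and both reservoirs: lateral diffusion
#' of the lipid fields through the finite-element Laplace-Beltrami
#' operator (`M dx/dt = -D K x` plus reaction), the Michaelis-Menten
#' conversion flux, first-order shuttling kinetics of the bound enzymes
#' (which do not diffuse laterally), and reservoir derivatives equal to
#' minus the surface integrals of net binding.
#'
#' @param state a [initial_state()] object.
#' @param t time (s), used to evaluate the signal schedule.
#' @param params a [polarity_params()] object.
#' @param mesh the [build_sphere_mesh()] the state lives on.
#' @return list with `dx_star`, `dx_0`, `da_R`, `da_X`, `db` (per node)
#'   and `dA_cyt`, `dB_cyt` (scalars), all in their natural units per
#'   second.
#' @export
assemble_rhs <- function(state, t, params, mesh) {
  fields <- c(state$x_star, state$x_0, state$a_R, state$a_X, state$b,
              state$A_cyt, state$B_cyt)
  if (any(!is.finite(fields)) || any(fields < -1e-9)) {
    stop("assemble_rhs: invalid state at t = ", t,
         " (min = ", min(fields), ", NaN = ", sum(!is.finite(fields)),
         "); state dump: mean phi = ",
         mean(state$x_star) / params$X_tot)
  }
  rec <- receptor_density(params$signal, t, mesh$vertices)
  cA <- state$A_cyt / params$V_cyt
  cB <- state$B_cyt / params$V_cyt
  F <- conversion_flux(pmax(state$x_star, 0), pmax(state$x_0, 0),
                       pmax(state$a_R, 0), pmax(state$a_X, 0),
                       pmax(state$b, 0), params)
  lap_xs <- -as.numeric(mesh$stiffness %*% state$x_star) / mesh$areas
  lap_x0 <- -as.numeric(mesh$stiffness %*% state$x_0) / mesh$areas
  da_R <- params$k_on_R * rec * cA - params$k_off_AR * state$a_R
  da_X <- params$k_on_X * state$x_star * cA - params$k_off_AX * state$a_X
  db <- params$k_on_B * state$x_0 * cB - params$k_off_B * state$b
  list(dx_star = params$D * lap_xs + F,
       dx_0 = params$D * lap_x0 - F,
       da_R = da_R, da_X = da_X, db = db,
       dA_cyt = -sum(mesh$areas * (da_R + da_X)),
       dB_cyt = -sum(mesh$areas * db))
}

#' Poisson noise configuration for the mean-field solver
#'
#' Perturbation events arrive as a Poisson process of rate `rate`; each
#' event modifies exactly one node, chosen uniformly.  Action
#' `"set_phi"` sets the node's activated fraction to `phi_set` (default:
#' the high equilibrium `phi_plus` of the instantaneous phase portrait);
#' `"gaussian"` multiplies the node's `x*` by `1 + amplitude * z`,
#' `z ~ N(0,1)`.  Either way the result is clipped to `[0, X_tot]` and
#' `x0` is updated to preserve the pointwise total.
#'
#' @param rate event rate (1/s).
#' @param action `"set_phi"` or `"gaussian"`.
#' @param phi_set target activated fraction for `"set_phi"`; `NULL` means
#'   the instantaneous `phi_plus`.
#' @param amplitude relative amplitude for `"gaussian"`.
#' @return a `noise_config` list.
#' @export
noise_config <- function(rate = 0, action = c("set_phi", "gaussian"),
                         phi_set = NULL, amplitude = 0.05) {
  action <- match.arg(action)
  stopifnot(rate >= 0, amplitude >= 0)
  structure(list(rate = rate, action = action, phi_set = phi_set,
                 amplitude = amplitude), class = "noise_config")
}

#' Apply one noise event to a membrane state
#'
#' @param state a `membrane_state`.
#' @param noise_cfg a [noise_config()].
#' @param params,mesh model parameters and mesh.
#' @return list with the perturbed `state` and the chosen `node`.
#'   Uses the current RNG state (seed management belongs to the caller).
#' @export
inject_noise <- function(state, noise_cfg, params, mesh) {
  n <- length(state$x_star)
  node <- sample.int(n, 1L)
  if (noise_cfg$action == "set_phi") {
    target <- noise_cfg$phi_set
    rec <- receptor_density(params$signal, state$time, mesh$vertices)
    if (is.null(target)) {
      rc <- reduced_coordinates(state$A_cyt, state$B_cyt, mean(rec), params)
      eq <- find_equilibria(rc$rho, rc$sigma, params)
      target <- max(eq$phi[eq$stable])
    }
    state$x_star[node] <- target * params$X_tot
    # the fluctuation carries its enzyme complement: slave the node's
    # bound enzymes to the new lipid state at current reservoir levels
    cA <- state$A_cyt / params$V_cyt
    cB <- state$B_cyt / params$V_cyt
    rec_n <- if (length(rec) > 1) rec[node] else rec
    state$a_R[node] <- ktil_R(params) * rec_n * cA
    state$a_X[node] <- ktil_X(params) * state$x_star[node] * cA
    state$b[node] <- ktil_B(params) * (params$X_tot - state$x_star[node]) * cB
    state$A_cyt <- params$A_tot -
      sum(mesh$areas * (state$a_R + state$a_X))
    state$B_cyt <- params$B_tot - sum(mesh$areas * state$b)
  } else {
    state$x_star[node] <- state$x_star[node] *
      (1 + noise_cfg$amplitude * rnorm(1))
  }
  state$x_star[node] <- min(max(state$x_star[node], 0), params$X_tot)
  state$x_0[node] <- params$X_tot - state$x_star[node]
  list(state = state, node = node)
}

# (exp(mu*h) - 1)/mu, stable for small mu*h
phi1_fun <- function(mu, h) {
  z <- mu * h
  ifelse(abs(z) < 1e-8, h * (1 + z / 2), expm1(z) / mu)
}

# Exact update of the A-enzyme pair (a_R, a_X, A_cyt) over h at frozen
# lipid fields and receptor profile: the subsystem is linear, so the two
# bound totals follow a 2x2 linear ODE solved by eigendecomposition and
# the nodal fields get the exactly integrated exponential forcing.
advance_enzymes_A <- function(st, rec, params, areas, h) {
  V <- params$V_cyt
  RT <- sum(areas * rec); XT <- sum(areas * st$x_star)
  kR <- params$k_on_R; kX <- params$k_on_X
  oR <- params$k_off_AR; oX <- params$k_off_AX
  S0 <- c(sum(areas * st$a_R), sum(areas * st$a_X))
  Q <- matrix(c(-kR * RT / V - oR, -kX * XT / V,
                -kR * RT / V, -kX * XT / V - oX), 2, 2)
  g <- c(kR * RT, kX * XT) * params$A_tot / V
  eg <- eigen(Q)
  lam <- eg$values; P <- eg$vectors
  Sinf <- tryCatch(-solve(Q, g), error = function(e) S0)
  w <- solve(P, S0 - Sinf)                 # S(t) = Sinf + P %*% (w * exp(lam t))
  # A_cyt(s) = c0 + sum_j cf_j exp(lam_j s)
  ac <- list(c0 = (params$A_tot - Sinf[1] - Sinf[2]) / V,
             cf = -(P[1, ] + P[2, ]) * w / V, lam = lam)
  # nodal update da/dt = -off*a + k*r_i*cA(s):
  # J(off) = exp(-off*h) * int_0^h exp(off*s) cA(s) ds
  Jof <- function(off) {
    val <- ac$c0 * phi1_fun(off, h)
    for (j in 1:2) val <- val + ac$cf[j] * phi1_fun(off + ac$lam[j], h)
    Re(val * exp(-off * h))
  }
  st$a_R <- st$a_R * exp(-oR * h) + kR * rec * Jof(oR)
  st$a_X <- st$a_X * exp(-oX * h) + kX * st$x_star * Jof(oX)
  st$a_R <- pmax(st$a_R, 0); st$a_X <- pmax(st$a_X, 0)
  st$A_cyt <- params$A_tot - sum(areas * (st$a_R + st$a_X))
  st
}

# Same for the single B species (scalar linear reservoir ODE).
advance_enzymes_B <- function(st, params, areas, h) {
  V <- params$V_cyt
  X0T <- sum(areas * st$x_0)
  kB <- params$k_on_B; oB <- params$k_off_B
  S0 <- sum(areas * st$b)
  lam <- -(kB * X0T / V + oB)
  Sinf <- if (lam != 0) kB * X0T * params$B_tot / V / (-lam) else S0
  w <- S0 - Sinf
  c0 <- (params$B_tot - Sinf) / V
  cf <- -w / V
  Jof <- ( c0 * phi1_fun(oB, h) + cf * phi1_fun(oB + lam, h) ) * exp(-oB * h)
  st$b <- pmax(st$b * exp(-oB * h) + kB * st$x_0 * Jof, 0)
  st$B_cyt <- params$B_tot - sum(areas * st$b)
  st
}

# RK2 (midpoint) step of the conversion term at frozen enzyme fields
advance_conversion <- function(st, params, h) {
  Xt <- params$X_tot
  F0 <- conversion_flux(st$x_star, st$x_0, st$a_R, st$a_X, st$b, params)
  xm <- pmin(pmax(st$x_star + 0.5 * h * F0, 0), Xt)
  Fm <- conversion_flux(xm, Xt - xm, st$a_R, st$a_X, st$b, params)
  st$x_star <- pmin(pmax(st$x_star + h * Fm, 0), Xt)
  st$x_0 <- Xt - st$x_star
  st
}

# reaction macro step: exact enzymes (h/2), conversion (h), exact enzymes (h/2)
reaction_step <- function(st, t0, h, params, mesh) {
  rec <- receptor_density(params$signal, t0 + h / 2, mesh$vertices)
  st <- advance_enzymes_A(st, rec, params, mesh$areas, h / 2)
  st <- advance_enzymes_B(st, params, mesh$areas, h / 2)
  st <- advance_conversion(st, params, h)
  st <- advance_enzymes_A(st, rec, params, mesh$areas, h / 2)
  st <- advance_enzymes_B(st, params, mesh$areas, h / 2)
  st
}

# one Strang step: reaction(h/2), Crank-Nicolson diffusion(h), reaction(h/2)
full_step <- function(st, t0, h, params, mesh, cache) {
  st <- reaction_step(st, t0, h / 2, params, mesh)
  fac <- cn_factor(cache, mesh, params$D, h)
  rhs <- mesh$areas * st$x_star - (params$D * h / 2) *
    as.numeric(mesh$stiffness %*% st$x_star)
  st$x_star <- as.numeric(Matrix::solve(fac, rhs))
  st$x_star <- pmin(pmax(st$x_star, 0), params$X_tot)
  st$x_0 <- params$X_tot - st$x_star
  st <- reaction_step(st, t0 + h / 2, h / 2, params, mesh)
  st$time <- t0 + h
  st
}

cn_factor <- function(cache, mesh, D, h) {
  key <- sprintf("h%.12e", h)
  fac <- cache[[key]]
  if (is.null(fac)) {
    n <- nrow(mesh$vertices)
    Amat <- Matrix::Diagonal(n, mesh$areas) + (D * h / 2) * mesh$stiffness
    fac <- Matrix::Cholesky(Matrix::forceSymmetric(Amat))
    cache[[key]] <- fac
  }
  fac
}

#' Integrate the mean-field equations on a spherical membrane
#'
#' Adaptive operator-splitting integrator: the linear enzyme-shuttling and
#' reservoir subsystem is advanced exactly at frozen lipid fields, the
#' Michaelis-Menten conversion term by an explicit midpoint rule, and
#' lateral diffusion implicitly (Crank-Nicolson with cached sparse
#' Cholesky factorizations), composed as a Strang splitting.  Step size is
#' controlled by step doubling on the activated fraction.  The pointwise
#' lipid total and both enzyme totals are conserved exactly by
#' construction (conservative diffusion stencil and reservoir closure).
#' Optional Poisson noise events are applied between solver segments at
#' their exact event times.
#'
#' @param state0 initial [initial_state()].
#' @param t_end final time (s).
#' @param params,mesh model parameters and mesh.
#' @param times snapshot times (default: 51 equally spaced points).
#' @param noise a [noise_config()] or `NULL`.
#' @param seed optional integer seed (noise events and any stochastic
#'   initial condition downstream; same seed and config give an identical
#'   trajectory).
#' @param rtol local error tolerance on `phi` per step.
#' @param dt_init,dt_max initial and maximal macro step (s).
#' @return object of class `polarity_trajectory`: list with `times`,
#'   `snapshots` (list of `membrane_state`), `events` (data.frame of
#'   noise events), `stats` (steps, rejects), `params`, `seed`.
#' @export
simulate_meanfield <- function(state0, t_end, params, mesh, times = NULL,
                               noise = NULL, seed = NULL, rtol = 1e-6,
                               dt_init = NULL, dt_max = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t0 <- state0$time
  if (is.null(times)) times <- seq(t0, t_end, length.out = 51L)
  times <- times[times >= t0 - 1e-12]
  if (is.null(dt_max)) dt_max <- (t_end - t0) / 20
  if (is.null(dt_init)) dt_init <- dt_max / 64
  lambda <- if (!is.null(noise) && noise$rate > 0) noise$rate else 0
  cache <- new.env(parent = emptyenv())
  # quantized step ladder keeps the factor cache small
  level <- max(0L, ceiling(2 * log2(dt_max / dt_init)))
  dt_of <- function(lev) dt_max * 2^(-lev / 2)

  st <- state0
  t <- t0
  snaps <- list(); snap_t <- numeric(0)
  ev <- list()
  nsteps <- 0L; nrej <- 0L
  next_event <- if (lambda > 0) t + rexp(1) / lambda else Inf
  snap_idx <- 1L
  # record an initial snapshot if requested at t0
  while (snap_idx <= length(times) && times[snap_idx] <= t + 1e-12) {
    snaps[[length(snaps) + 1L]] <- st; snap_t <- c(snap_t, t)
    snap_idx <- snap_idx + 1L
  }
  while (t < t_end - 1e-12) {
    t_break <- min(if (snap_idx <= length(times)) times[snap_idx] else Inf,
                   t_end)
    while (t < t_break - 1e-12) {
      # noise events fire at the first step boundary past their Poisson
      # arrival time, so factor caching stays effective
      while (t >= next_event) {
        st$time <- t
        res <- inject_noise(st, noise, params, mesh)
        st <- res$state
        ev[[length(ev) + 1L]] <- data.frame(time = t, node = res$node,
                                            action = noise$action)
        next_event <- next_event + rexp(1) / lambda
      }
      h <- min(dt_of(level), t_break - t)
      ok <- FALSE
      y1 <- tryCatch(full_step(st, t, h, params, mesh, cache),
                     error = function(e) NULL)
      if (!is.null(y1)) {
        yh <- tryCatch(full_step(st, t, h / 2, params, mesh, cache),
                       error = function(e) NULL)
        y2 <- if (is.null(yh)) NULL else
          tryCatch(full_step(yh, t + h / 2, h / 2, params, mesh, cache),
                   error = function(e) NULL)
        if (!is.null(y2)) {
          err <- max(abs(y1$x_star - y2$x_star)) / params$X_tot / 3
          errA <- abs(y1$A_cyt - y2$A_cyt) / max(params$A_tot, 1) / 3
          err <- max(err, errA)
          if (is.finite(err) && err <= rtol &&
              y2$A_cyt > -1e-9 * params$A_tot &&
              y2$B_cyt > -1e-9 * params$B_tot) {
            st <- y2; t <- t + h; ok <- TRUE
            nsteps <- nsteps + 1L
            if (err < 0.1 * rtol && level > 0L) level <- level - 1L
          }
        }
      }
      if (!ok) {
        nrej <- nrej + 1L
        level <- level + 2L
        if (dt_of(level) < 1e-10 * max(t_end - t0, 1))
          stop("step-size collapse at t = ", t,
               ": the conversion term is too stiff for the requested tolerance")
      }
    }
    t <- t_break
    if (snap_idx <= length(times) && abs(t - times[snap_idx]) <= 1e-9) {
      st$time <- t
      snaps[[length(snaps) + 1L]] <- st; snap_t <- c(snap_t, t)
      snap_idx <- snap_idx + 1L
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(time = numeric(0), node = integer(0), action = character(0))
  structure(list(times = snap_t, snapshots = snaps, events = events,
                 stats = list(steps = nsteps, rejected = nrej),
                 params = params, seed = seed),
            class = "polarity_trajectory")
}

#' @export
print.polarity_trajectory <- function(x, ...) {
  cat(sprintf("mean-field trajectory: %d snapshots over t = [%.4g, %.4g] s, %d steps (%d rejected), %d noise events\n",
              length(x$times), min(x$times), max(x$times),
              x$stats$steps, x$stats$rejected, nrow(x$events)))
  invisible(x)
}

#' Scalar time series of a trajectory
#'
#' Per-snapshot summary: mean and spatial variance of the activated
#' fraction (area weighted), reservoir counts, the instantaneous reduced
#' coordinates and, where the portrait is bistable, `delta_V` and the
#' patch count above the instantaneous barrier `phi_u`.
#'
#' @param traj a [simulate_meanfield()] trajectory.
#' @param params,mesh model parameters and mesh.
#' @return data.frame with one row per snapshot.
#' @export
trajectory_summary <- function(traj, params, mesh) {
  w <- mesh$areas / sum(mesh$areas)
  rows <- lapply(seq_along(traj$times), function(i) {
    st <- traj$snapshots[[i]]
    phi <- st$x_star / params$X_tot
    mp <- sum(w * phi)
    vp <- sum(w * (phi - mp)^2)
    rec <- receptor_density(params$signal, st$time, mesh$vertices)
    rc <- reduced_coordinates(st$A_cyt, st$B_cyt, mean(rec), params)
    dv <- delta_V_at(rc$rho, rc$sigma, params)
    npatch <- NA_integer_
    if (is.finite(dv)) {
      eq <- find_equilibria(rc$rho, rc$sigma, params)
      nr <- named_roots(eq)
      npatch <- nrow(detect_patches(st, mesh, threshold = nr$phi_u,
                                    params = params))
    }
    data.frame(time = st$time, mean_phi = mp, var_phi = vp,
               A_cyt = st$A_cyt, B_cyt = st$B_cyt,
               rho = rc$rho, sigma = rc$sigma, delta_V = dv,
               n_patches = npatch)
  })
  do.call(rbind, rows)
}

#' Kymograph along the great-circle path
#'
#' @param traj a [simulate_meanfield()] trajectory.
#' @param mesh the mesh it was computed on.
#' @return numeric matrix: rows are snapshot times, columns the
#'   great-circle nodes ordered by arc length; entries are the activated
#'   fraction `x*/X_tot`.  Row names are times, column names the node
#'   indices.
#' @export
kymograph <- function(traj, mesh) {
  if (length(traj$times) == 0) stop("empty trajectory")
  path <- mesh$equator
  Xt <- traj$snapshots[[1]]$x_star + traj$snapshots[[1]]$x_0
  m <- t(vapply(traj$snapshots,
                function(st) (st$x_star / (st$x_star + st$x_0))[path],
                numeric(length(path))))
  rownames(m) <- signif(traj$times, 8)
  colnames(m) <- path
  m
}

#' @describeIn kymograph plot a kymograph as an image (angle vs time).
#' @param mat a kymograph matrix.
#' @param ... passed to [graphics::image()].
#' @export
plot_kymograph <- function(mat, ...) {
  tt <- as.numeric(rownames(mat))
  image(tt, seq_len(ncol(mat)), mat, xlab = "time (s)",
        ylab = "perimeter node", col = hcl.colors(64, "Blue-Red"), ...)
  invisible(mat)
}

#' Connected activated patches of a membrane state
#'
#' Connected components (under mesh adjacency) of the node set whose
#' activated fraction exceeds `threshold`, with areas and centroids,
#' sorted by area descending.
#'
#' @param state a `membrane_state`, or a per-node numeric vector of
#'   activated fractions.
#' @param mesh the mesh.
#' @param threshold activated-fraction threshold; default is the barrier
#'   `phi_u` of the instantaneous phase portrait (requires `params` and a
#'   bistable portrait).
#' @param params needed only for the default threshold.
#' @return data.frame with columns `id`, `area`, `n_nodes`, `cx`, `cy`,
#'   `cz` (area-weighted centroid direction); the member nodes are in
#'   `attr(, "nodes")` (list of integer vectors).
#' @export
detect_patches <- function(state, mesh, threshold = NULL, params = NULL) {
  phi <- if (inherits(state, "membrane_state"))
    state$x_star / (state$x_star + state$x_0) else as.numeric(state)
  if (is.null(threshold)) {
    if (is.null(params) || !inherits(state, "membrane_state"))
      stop("default threshold needs a membrane_state and params")
    rec <- receptor_density(params$signal, state$time, mesh$vertices)
    rc <- reduced_coordinates(state$A_cyt, state$B_cyt, mean(rec), params)
    nr <- named_roots(find_equilibria(rc$rho, rc$sigma, params))
    if (!nr$bistable)
      stop("portrait not bistable; supply an explicit threshold")
    threshold <- nr$phi_u
  }
  above <- which(phi > threshold)
  comp <- integer(length(phi))
  nodes_list <- list()
  cid <- 0L
  inset <- logical(length(phi)); inset[above] <- TRUE
  for (s in above) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid; members <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (u in mesh$neighbors[[v]]) {
        if (inset[u] && comp[u] == 0L) {
          comp[u] <- cid; queue <- c(queue, u); members <- c(members, u)
        }
      }
    }
    nodes_list[[cid]] <- sort(members)
  }
  if (cid == 0L) {
    out <- data.frame(id = integer(0), area = numeric(0),
                      n_nodes = integer(0), cx = numeric(0),
                      cy = numeric(0), cz = numeric(0))
    attr(out, "nodes") <- list()
    return(out)
  }
  rows <- lapply(seq_len(cid), function(k) {
    idx <- nodes_list[[k]]
    w <- mesh$areas[idx]
    ctr <- colSums(mesh$vertices[idx, , drop = FALSE] * w) / sum(w)
    ctr <- ctr / sqrt(sum(ctr^2))
    data.frame(id = k, area = sum(w), n_nodes = length(idx),
               cx = ctr[1], cy = ctr[2], cz = ctr[3])
  })
  out <- do.call(rbind, rows)
  ord <- order(out$area, decreasing = TRUE)
  out <- out[ord, , drop = FALSE]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "nodes") <- nodes_list[ord]
  out
}

#' Discrete effective energy functional
#'
#' The Lyapunov functional of the reduced spatial dynamics at frozen
#' reduced coordinates: `E = D/2 * phi' K phi + sum_i M_i V(phi_i)`
#' (gradient-square term through the stiffness matrix plus the effective
#' potential integrated with the lumped mass).  With noise off and frozen
#' reservoirs the mean-field dynamics descends this functional.
#'
#' @param phi per-node activated fraction.
#' @param mesh the mesh.
#' @param rho,sigma frozen reduced coordinates.
#' @param params a [polarity_params()] object.
#' @param V_interp optional precomputed potential interpolator (function
#'   of phi), e.g. from [stats::splinefun()] on [effective_potential()].
#' @return the scalar energy (um^2/s units times the dimensionless field).
#' @export
effective_energy <- function(phi, mesh, rho, sigma, params,
                             V_interp = NULL) {
  if (is.null(V_interp)) {
    tab <- effective_potential(seq(0, 1, length.out = 801L), rho, sigma,
                               params)
    V_interp <- stats::splinefun(tab$phi, tab$V, method = "natural")
  }
  grad_term <- params$D / 2 *
    sum(phi * as.numeric(mesh$stiffness %*% phi))
  grad_term + sum(mesh$areas * V_interp(phi))
}
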
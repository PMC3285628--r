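#' Build a reaction lattice from a sphere mesh
#'
#' Sites are the mesh nodes, neighbour relations are the mesh edges and
#' site areas are the lumped node areas, so the stochastic engine and the
#' mean-field solver share one discretization of the membrane.
#'
#' @param mesh a [build_sphere_mesh()] object.
#' @return object of class `polarity_lattice`: `n_sites`, `areas`,
#'   `neighbors` (list), `nbr`/`nbr_ptr` (0-based CSR used by the C++
#'   core), `S_area` (total lattice area), `mesh` (the source mesh).
#' @export
build_lattice <- function(mesh) {
  stopifnot(inherits(mesh, "sphere_mesh"))
  nbr <- unlist(lapply(mesh$neighbors, function(v) v - 1L))
  ptr <- cumsum(c(0L, lengths(mesh$neighbors)))
  structure(list(n_sites = nrow(mesh$vertices), areas = mesh$areas,
                 neighbors = mesh$neighbors,
                 nbr = as.integer(nbr), nbr_ptr = as.integer(ptr),
                 S_area = sum(mesh$areas), mesh = mesh),
            class = "polarity_lattice")
}

#' @export
print.polarity_lattice <- function(x, ...) {
  cat(sprintf("reaction lattice: %d sites, area %.4g um^2\n",
              x$n_sites, x$S_area))
  invisible(x)
}

#' Integer lattice state for the stochastic engine
#'
#' Rounds the mean-field densities at activated fraction `phi` into
#' integer copy numbers per site and puts the enzyme balance into the
#' reservoirs.  Bound-enzyme counts start at their slaved equilibria
#' (rounded), the reservoirs close the conservation laws exactly.
#'
#' @param lattice a [build_lattice()] object.
#' @param params a [polarity_params()] object.
#' @param phi activated fraction: scalar or per-site.
#' @param receptor per-site activated-receptor density; defaults to the
#'   signal schedule at `time`.
#' @param time time stamp (s).
#' @return object of class `lattice_state`: integer matrix `counts`
#'   (sites x 5: `XS`, `X0`, `AR`, `AX`, `B`), integers `A_cyt`,
#'   `B_cyt`, per-site `receptor`, `time`.
#' @export
lattice_state <- function(lattice, params, phi = 0, receptor = NULL,
                          time = 0) {
  n <- lattice$n_sites
  phi <- rep_len(phi, n)
  if (is.null(receptor))
    receptor <- receptor_density(params$signal, time, lattice$mesh$vertices)
  receptor <- rep_len(receptor, n)
  xs <- round(phi * params$X_tot * lattice$areas)
  x0 <- round(params$X_tot * lattice$areas) - xs
  # the lattice's own total area is the membrane area of the discrete model
  p_lat <- params
  p_lat$S_area <- lattice$S_area
  p_lat$chi <- p_lat$S_area / p_lat$V_cyt
  eq <- enzyme_equilibria(phi * params$X_tot, (1 - phi) * params$X_tot,
                          receptor, p_lat, weights = lattice$areas)
  ar <- round(eq$a_R * lattice$areas)
  ax <- round(eq$a_X * lattice$areas)
  b <- round(eq$b * lattice$areas)
  A_cyt <- params$A_tot - sum(ar) - sum(ax)
  B_cyt <- params$B_tot - sum(b)
  if (A_cyt < 0 || B_cyt < 0)
    stop("enzyme totals too small for the requested bound state")
  counts <- cbind(XS = xs, X0 = x0, AR = ar, AX = ax, B = b)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, A_cyt = A_cyt, B_cyt = B_cyt,
                 receptor = receptor, time = time),
            class = "lattice_state")
}

#' Reaction and diffusion propensities of a lattice state
#'
#' Reference implementation of the transition-rate table: per-site
#' Michaelis-Menten conversion evaluated on counts (Michaelis constants
#' scaled by site area), enzyme binding proportional to the integer
#' reservoir counts, first-order unbinding, and per-molecule diffusion
#' leave rate `D * N / S_area` split evenly among the neighbours.  The
#' C++ Gillespie core computes the same quantities incrementally; this
#' function is the readable (and testable) specification.
#'
#' @param state a [lattice_state()].
#' @param params a [polarity_params()] object.
#' @param lattice a [build_lattice()] object.
#' @return list with `reaction` (sites x 8 matrix: activation,
#'   deactivation, bind/unbind for AR, AX, B), `diffusion` (sites x 2:
#'   total leave propensity of `X*` and `X0`), and `total`.
#' @export
compute_propensities <- function(state, params, lattice) {
  cm <- state$counts
  if (any(cm < 0) || state$A_cyt < 0 || state$B_cyt < 0)
    stop("negative copy number: invariant violation")
  s <- lattice$areas
  hop <- if (lattice$n_sites > 1) params$D * lattice$n_sites / lattice$S_area else 0
  act <- params$k_cat_A * (cm[, "AR"] + cm[, "AX"]) * cm[, "X0"] /
    (params$K_A * s + cm[, "X0"])
  deact <- params$k_cat_B * cm[, "B"] * cm[, "XS"] /
    (params$K_B * s + cm[, "XS"])
  bind_ar <- params$k_on_R * state$receptor * s * state$A_cyt / params$V_cyt
  unb_ar <- params$k_off_AR * cm[, "AR"]
  bind_ax <- params$k_on_X * cm[, "XS"] * state$A_cyt / params$V_cyt
  unb_ax <- params$k_off_AX * cm[, "AX"]
  bind_b <- params$k_on_B * cm[, "X0"] * state$B_cyt / params$V_cyt
  unb_b <- params$k_off_B * cm[, "B"]
  reaction <- cbind(activation = act, deactivation = deact,
                    bind_AR = bind_ar, unbind_AR = unb_ar,
                    bind_AX = bind_ax, unbind_AX = unb_ax,
                    bind_B = bind_b, unbind_B = unb_b)
  diffusion <- cbind(XS = hop * cm[, "XS"], X0 = hop * cm[, "X0"])
  list(reaction = reaction, diffusion = diffusion,
       total = sum(reaction) + sum(diffusion))
}

#' Exact Gillespie simulation of the lattice master equation
#'
#' Direct-method stochastic simulation: waiting times are exponential in
#' the total propensity, events are chosen proportionally to their
#' rates, and propensities are updated incrementally (Fenwick-tree
#' bookkeeping, with the reservoir-coupled binding channels factored so a
#' reservoir change is O(1)).  Uses R's RNG: the same seed and
#' configuration reproduce the identical event sequence.
#'
#' @param state0 a [lattice_state()].
#' @param t_max end time (s).
#' @param params a [polarity_params()] object.
#' @param lattice a [build_lattice()] object.
#' @param seed optional integer seed.
#' @param snapshot_times times at which to record the full state
#'   (default 101 equally spaced).
#' @param record_events keep an event log (time, site, channel)?  Capped
#'   at `max_log` entries.
#' @param max_events safety cap on the number of events.
#' @param max_log event-log cap.
#' @return object of class `ssa_trajectory`: `times`, `counts` (array
#'   time x site x species), `reservoirs` (matrix time x 2), `n_events`,
#'   `final` (a `lattice_state`), `absorbed` flag and optionally
#'   `events`.
#' @export
gillespie_run <- function(state0, t_max, params, lattice, seed = NULL,
                          snapshot_times = NULL, record_events = FALSE,
                          max_events = 5e8, max_log = 2e6) {
  stopifnot(inherits(state0, "lattice_state"), t_max > state0$time)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(snapshot_times))
    snapshot_times <- seq(state0$time, t_max, length.out = 101L)
  pars <- params[c("k_cat_A", "k_cat_B", "K_A", "K_B", "k_on_R", "k_on_X",
                   "k_on_B", "k_off_AR", "k_off_AX", "k_off_B", "V_cyt",
                   "D")]
  res <- .ssa_core(state0$counts, state0$A_cyt, state0$B_cyt,
                   lattice$areas, state0$receptor,
                   lattice$nbr, lattice$nbr_ptr, pars,
                   state0$time, t_max, snapshot_times,
                   max_events, record_events, as.integer(max_log))
  arr <- array(res$snapshots,
               dim = c(length(snapshot_times), lattice$n_sites, 5L),
               dimnames = list(NULL, NULL, c("XS", "X0", "AR", "AX", "B")))
  final <- structure(list(counts = res$final_counts,
                          A_cyt = res$A_cyt, B_cyt = res$B_cyt,
                          receptor = state0$receptor, time = res$t_end),
                     class = "lattice_state")
  colnames(final$counts) <- c("XS", "X0", "AR", "AX", "B")
  out <- list(times = snapshot_times, counts = arr,
              reservoirs = res$reservoirs, n_events = res$n_events,
              final = final, absorbed = res$absorbed, seed = seed,
              lattice_n = lattice$n_sites)
  if (record_events) out$events <- res$events
  structure(out, class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf("SSA trajectory: %d sites, %d snapshots to t = %.4g s, %.3g events%s\n",
              x$lattice_n, length(x$times), max(x$times), x$n_events,
              if (x$absorbed) " (absorbed)" else ""))
  invisible(x)
}

#' Activated fraction per site of an SSA snapshot
#'
#' @param traj an [gillespie_run()] trajectory.
#' @param i snapshot index.
#' @return per-site `XS / (XS + X0)`.
#' @export
ssa_phi <- function(traj, i) {
  xs <- traj$counts[i, , "XS"]; x0 <- traj$counts[i, , "X0"]
  tot <- xs + x0
  ifelse(tot > 0, xs / tot, 0)
}

#' Patch lifetime and size statistics of a stochastic trajectory
#'
#' Detects activated patches (shared detector with the mean-field module)
#' on every snapshot and links them through time by centroid proximity:
#' a patch in one snapshot continues an existing track if its centroid
#' lies within `link_radius` of the track's last centroid.  Reports the
#' lifetime and maximum-size distributions and the fraction of snapshots
#' with at least one patch.
#'
#' @param traj an [gillespie_run()] trajectory.
#' @param lattice the lattice it ran on.
#' @param threshold activated-fraction threshold defining a patch.
#' @param min_nodes ignore components smaller than this many sites.
#' @param link_radius linking distance (um); default one mean site
#'   spacing times 1.5.
#' @return list with `tracks` (data.frame: id, t_start, t_end, lifetime,
#'   max_area), `n_patches` (per-snapshot count), `fraction_occupied`
#'   (fraction of snapshots with >= 1 patch), `times`.
#' @export
intermittency_metrics <- function(traj, lattice, threshold = 0.5,
                                  min_nodes = 1L, link_radius = NULL) {
  mesh <- lattice$mesh
  if (is.null(link_radius))
    link_radius <- 1.5 * sqrt(mean(lattice$areas))
  n_t <- length(traj$times)
  open <- list()     # open tracks: list(centroid, t_start, t_last, max_area)
  closed <- list()
  n_patches <- integer(n_t)
  for (i in seq_len(n_t)) {
    pats <- detect_patches(ssa_phi(traj, i), mesh, threshold = threshold)
    pats <- pats[pats$n_nodes >= min_nodes, , drop = FALSE]
    n_patches[i] <- nrow(pats)
    used <- rep(FALSE, length(open))
    new_open <- list()
    if (nrow(pats)) {
      for (k in seq_len(nrow(pats))) {
        ctr <- c(pats$cx[k], pats$cy[k], pats$cz[k]) * mesh$R
        best <- 0; bestd <- Inf
        for (j in seq_along(open)) {
          if (used[j]) next
          d <- sqrt(sum((ctr - open[[j]]$centroid)^2))
          if (d < bestd) { bestd <- d; best <- j }
        }
        if (best > 0 && bestd <= link_radius) {
          tr <- open[[best]]
          tr$centroid <- ctr; tr$t_last <- traj$times[i]
          tr$max_area <- max(tr$max_area, pats$area[k])
          new_open[[length(new_open) + 1L]] <- tr
          used[best] <- TRUE
        } else {
          new_open[[length(new_open) + 1L]] <-
            list(centroid = ctr, t_start = traj$times[i],
                 t_last = traj$times[i], max_area = pats$area[k])
        }
      }
    }
    for (j in seq_along(open)) if (!used[j])
      closed[[length(closed) + 1L]] <- open[[j]]
    open <- new_open
  }
  for (j in seq_along(open)) closed[[length(closed) + 1L]] <- open[[j]]
  tracks <- if (length(closed)) {
    do.call(rbind, lapply(seq_along(closed), function(j) {
      tr <- closed[[j]]
      data.frame(id = j, t_start = tr$t_start, t_end = tr$t_last,
                 lifetime = tr$t_last - tr$t_start, max_area = tr$max_area)
    }))
  } else {
    data.frame(id = integer(0), t_start = numeric(0), t_end = numeric(0),
               lifetime = numeric(0), max_area = numeric(0))
  }
  list(tracks = tracks, n_patches = n_patches,
       fraction_occupied = mean(n_patches > 0), times = traj$times)
}
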
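#' Self-consistent uniform stationary state
#'
#' Iterates between the uniform enzyme-shuttling equilibria and the
#' chemical equilibria of the reduced dynamics until the activated
#' fraction converges to a stable uniform stationary state.
#'
#' @param params a [polarity_params()] object.
#' @param rho_R uniform activated-receptor density (molecules/um^2).
#' @param phi0 starting guess; `branch` picks the lowest (`"low"`) or
#'   highest (`"high"`) stable root at each iterate.
#' @param branch `"low"` or `"high"`.
#' @return list with `phi`, `rho`, `sigma`, `A_cyt`, `B_cyt`.
#' @export
uniform_steady_state <- function(params, rho_R = 0, phi0 = 0,
                                 branch = c("low", "high")) {
  branch <- match.arg(branch)
  phi <- phi0
  for (i in 1:200) {
    eq <- enzyme_equilibria(phi * params$X_tot, (1 - phi) * params$X_tot,
                            rho_R, params, weights = params$S_area)
    rc <- reduced_coordinates(eq$A_cyt, eq$B_cyt, rho_R, params)
    roots <- find_equilibria(rc$rho, rc$sigma, params)
    st <- roots$phi[roots$stable]
    phi_new <- if (branch == "low") min(st) else max(st)
    if (abs(phi_new - phi) < 1e-13) break
    phi <- phi_new
  }
  list(phi = phi, rho = rc$rho, sigma = rc$sigma,
       A_cyt = eq$A_cyt, B_cyt = eq$B_cyt)
}

preset_dir <- function() system.file("extdata", "presets",
                                     package = "polarisim")

#' Load a scenario preset
#'
#' Presets bundle a parameter set, a stimulation schedule and scenario
#' settings for the four biological cases: `"chemotaxis"` (Dictyostelium
#' PIP2/PIP3 with PI3K/PTEN), `"epithelial"` (apico-basal polarity),
#' `"yeast"` (Cdc42/GEF polarization) and `"ras"` (Ras-GTP nanodomains).
#' Every numeric entry in a preset file carries a unit and a provenance
#' note; loading fails if either is missing.  The loaded parameter set is
#' checked to lie in the regime the scenario needs (via
#' [classify_region()]) before it is returned.
#'
#' @param name preset name.
#' @param overrides named list; entries override scenario settings
#'   (`scenario.key`) or parameters (plain key), e.g.
#'   `list(A_tot = 5e4, "scenario.t_end" = 100)`.
#' @return list with `name`, `params` (a [polarity_params()]),
#'   `scenario` (list of scenario settings).
#' @export
load_preset <- function(name, overrides = list()) {
  path <- file.path(preset_dir(), paste0(name, ".yaml"))
  if (!file.exists(path)) stop("unknown preset: ", name)
  raw <- yaml::read_yaml(path)
  need_meta <- function(block, where) {
    for (nm in names(block)) {
      e <- block[[nm]]
      if (is.list(e) && !is.null(e$value)) {
        if (is.null(e$unit) || is.null(e$provenance))
          stop("preset entry '", where, ".", nm,
               "' lacks unit or provenance")
      }
    }
  }
  need_meta(raw$parameters, "parameters")
  need_meta(raw$signal, "signal")
  need_meta(raw$scenario, "scenario")
  val <- function(e) if (is.list(e)) as.numeric(e$value) else e
  pvals <- lapply(raw$parameters, val)
  for (nm in names(overrides)) {
    if (nm %in% names(pvals)) pvals[[nm]] <- overrides[[nm]]
  }
  params <- do.call(polarity_params, pvals)
  sg <- lapply(raw$signal, val)
  params$signal <- switch(sg$type,
    none = signal_schedule("constant", rho_R = 0),
    constant = signal_schedule("constant",
      rho_R = receptor_from_sigma(sg$sigma, params)),
    adapting = signal_schedule("adapting",
      rho_R = receptor_from_sigma(sg$sigma_on, params),
      t_on = sg$t_on, tau = sg$tau, plateau = sg$plateau_fraction),
    stop("unknown signal type in preset"))
  sc <- lapply(raw$scenario, val)
  for (nm in names(overrides)) {
    key <- sub("^scenario\\.", "", nm)
    if (grepl("^scenario\\.", nm)) sc[[key]] <- overrides[[nm]]
  }
  structure(list(name = raw$name, params = params, scenario = sc),
            class = "polarity_preset")
}

#' @export
print.polarity_preset <- function(x, ...) {
  cat("scenario preset:", x$name, "- engine", x$scenario$engine, "\n")
  print(x$params)
  invisible(x)
}

# conservation / determinism invariant block for reports
invariant_block <- function(traj, params, mesh) {
  st0 <- traj$snapshots[[1]]; stf <- traj$snapshots[[length(traj$snapshots)]]
  totX0 <- sum(mesh$areas * (st0$x_star + st0$x_0))
  totXf <- sum(mesh$areas * (stf$x_star + stf$x_0))
  consA <- abs(sum(mesh$areas * (stf$a_R + stf$a_X)) + stf$A_cyt -
                 params$A_tot) / params$A_tot
  consB <- abs(sum(mesh$areas * stf$b) + stf$B_cyt - params$B_tot) /
    params$B_tot
  list(X_conservation = abs(totXf - totX0) / totX0,
       A_conservation = consA, B_conservation = consB,
       pass = abs(totXf - totX0) / totX0 < 1e-6 && consA < 1e-6 &&
         consB < 1e-6)
}

#' Run the eukaryotic chemotaxis scenario
#'
#' Reproduces the uniform-stimulation protocol: the membrane rests in the
#' unactivated-rich phase; at `t_on` receptor activation switches on and
#' then adapts exponentially to a residual plateau; 5% multiplicative
#' Gaussian roughness is imposed at time zero and Poisson node-flip noise
#' runs throughout.  The report tests the two-stage signature: a
#' spatially uniform transient rise and decay of the mean activated
#' fraction (spatial variance below `var_lo`), followed - once the
#' enzyme-ratio trajectory has re-entered the bistable region - by
#' nucleation of localized activated patches (variance above `var_hi`
#' while the mean is below its uniform-stage peak), Lifshitz-Slyozov
#' coarsening towards a single patch and self-tuning of `delta_V`
#' towards zero.
#'
#' @param config a preset from [load_preset()] (`"chemotaxis"`).
#' @param seed integer seed.
#' @return object of class `chemotaxis_report`: `summary` (time series),
#'   `kymograph`, `two_stage`, `stage1` (uniform-phase peak), `stage2`
#'   (detection time), `final_n_patches`, `delta_V_end_ratio`,
#'   `invariants`, `trajectory`, `mesh`, `config`, `seed`.
#' @export
run_chemotaxis <- function(config, seed = 1L) {
  stopifnot(config$scenario$engine == "meanfield")
  p <- config$params
  sc <- config$scenario
  mesh <- build_sphere_mesh(sc$mesh_level, R = p$R)
  rest <- uniform_steady_state(p, rho_R = 0, branch = "low")
  set.seed(seed)
  st <- initial_state(mesh, p, phi = rest$phi,
                      noise_rel = sc$init_noise_rel, time = 0)
  nz <- noise_config(rate = sc$noise_rate, action = "set_phi",
                     phi_set = sc$noise_phi_set)
  tr <- simulate_meanfield(st, sc$t_end, p, mesh,
                           times = seq(0, sc$t_end, by = sc$snapshot_dt),
                           noise = nz, rtol = sc$rtol)
  s <- trajectory_summary(tr, p, mesh)
  lo <- sc$var_lo; hi <- sc$var_hi
  uniform <- s$var_phi < lo
  peak <- max(s$mean_phi[uniform])
  t_peak <- s$time[uniform][which.max(s$mean_phi[uniform])]
  i2 <- which(s$var_phi > hi & s$time > t_peak)[1]
  two_stage <- !is.na(i2) && s$mean_phi[i2] < peak
  # delta_V self-tuning: compare the end value with the value right
  # after nucleation (first bistable snapshot past stage 2)
  dv_ratio <- NA_real_
  if (!is.na(i2)) {
    dv_post <- abs(s$delta_V[i2])
    dv_end <- abs(tail(s$delta_V[is.finite(s$delta_V)], 1))
    if (is.finite(dv_post) && dv_post > 0) dv_ratio <- dv_end / dv_post
  }
  # final patch count at the cap scale: single-node components are
  # noise-event transients, not phase domains
  stf <- tr$snapshots[[length(tr$snapshots)]]
  fin_pat <- tryCatch({
    pats <- detect_patches(stf, mesh, params = p)
    sum(pats$n_nodes >= 2L)
  }, error = function(e) NA_integer_)
  structure(list(summary = s, kymograph = kymograph(tr, mesh),
                 two_stage = two_stage,
                 stage1 = list(peak = peak, t_peak = t_peak),
                 stage2 = list(t_detect = if (is.na(i2)) NA_real_ else s$time[i2]),
                 final_n_patches = fin_pat,
                 delta_V_end_ratio = dv_ratio,
                 invariants = invariant_block(tr, p, mesh),
                 trajectory = tr, mesh = mesh, config = config,
                 seed = seed),
            class = "chemotaxis_report")
}

#' @export
print.chemotaxis_report <- function(x, ...) {
  cat(sprintf("chemotaxis run (seed %d): two_stage = %s, stage-1 peak %.3f @ %.4g s, stage-2 at %.4g s, final patches %d, |dV| end ratio %.3g\n",
              x$seed, x$two_stage, x$stage1$peak, x$stage1$t_peak,
              x$stage2$t_detect, x$final_n_patches, x$delta_V_end_ratio))
  invisible(x)
}

# moment-based cap area: reservoir-consistent estimate of the activated
# cap from the mean activated fraction and the instantaneous phases
cap_area_moment <- function(state, mesh, params) {
  rec <- receptor_density(params$signal, state$time, mesh$vertices)
  rc <- reduced_coordinates(state$A_cyt, state$B_cyt, mean(rec), params)
  nr <- named_roots(find_equilibria(rc$rho, rc$sigma, params))
  phi <- state$x_star / (state$x_star + state$x_0)
  mp <- sum(mesh$areas * phi) / sum(mesh$areas)
  if (!nr$bistable) return(NA_real_)
  sum(mesh$areas) * (mp - nr$phi_minus) / (nr$phi_plus - nr$phi_minus)
}

#' Run the epithelial polarization scenario
#'
#' The membrane starts uniformly in the activated-rich (PIP3-like) phase
#' under constant uniform receptor activation; a circular germ of the
#' unactivated-rich (PIP2-like) phase of geodesic radius `r` is placed at
#' a pole (heterogeneous nucleation by an active process) and the
#' deterministic dynamics decides its fate.  Germs below the critical
#' radius dissolve; larger germs grow into a stable polarized two-cap
#' state.  The report classifies each radius, brackets the critical
#' radius, and compares the equilibrium activated-cap area of the
#' largest polarized run against the sharp-interface prediction of
#' [patch_area_ratio()] evaluated with the mesh's discrete total area.
#'
#' @param config a preset from [load_preset()] (`"epithelial"`).
#' @param radii germ radii to sweep (um); default from the preset.
#' @param seed integer seed (the scenario is deterministic; the seed is
#'   recorded for provenance only).
#' @return object of class `epithelial_report`: `outcomes` (data.frame
#'   radius/outcome/final cap areas), `r_c` (bracket midpoint),
#'   `monotone` flag, `cap_area_final`, `cap_area_predicted`,
#'   `mesh_cell_area`, `config`, `seed`.
#' @export
run_epithelial <- function(config, radii = NULL, seed = 1L) {
  stopifnot(config$scenario$engine == "meanfield")
  p <- config$params
  sc <- config$scenario
  mesh <- build_sphere_mesh(sc$mesh_level, R = p$R)
  if (is.null(radii))
    radii <- seq(sc$radius_min, sc$radius_max, length.out = sc$radius_n)
  rho_R <- p$signal$rho_R
  hi <- uniform_steady_state(p, rho_R = rho_R, phi0 = 1, branch = "high")
  # discrete-consistent sharp-interface prediction
  p_mesh <- p; p_mesh$S_area <- sum(mesh$areas)
  p_mesh$chi <- p_mesh$S_area / p_mesh$V_cyt
  pred <- patch_area_ratio(p_mesh, sigma_from_receptor(rho_R, p_mesh))
  phi_in <- if (pred$possible) pred$phi_minus else 0.01
  rows <- list(); caps <- rep(NA_real_, length(radii))
  set.seed(seed)
  for (k in seq_along(radii)) {
    st <- initial_state(mesh, p, phi = hi$phi,
                        germ = list(center = c(0, 0, 1), radius = radii[k],
                                    phi_in = phi_in))
    tr <- simulate_meanfield(st, sc$t_end, p, mesh,
                             times = c(0, sc$t_end / 2, sc$t_end),
                             rtol = sc$rtol)
    stf <- tr$snapshots[[length(tr$snapshots)]]
    phi_f <- stf$x_star / (stf$x_star + stf$x_0)
    w <- mesh$areas / sum(mesh$areas)
    mp <- sum(w * phi_f)
    vp <- sum(w * (phi_f - mp)^2)
    polarized <- vp > sc$polarized_var
    caps[k] <- cap_area_moment(stf, mesh, p)
    rows[[k]] <- data.frame(radius = radii[k],
                            outcome = if (polarized) "polarized" else "dissolved",
                            var_phi = vp, mean_phi = mp,
                            cap_area = caps[k])
  }
  outcomes <- do.call(rbind, rows)
  pol <- outcomes$outcome == "polarized"
  trans <- which(diff(as.integer(pol)) != 0)
  monotone <- length(trans) == 1L && all(diff(as.integer(pol)) >= 0)
  r_c <- if (length(trans) >= 1L)
    mean(radii[c(trans[1], trans[1] + 1L)]) else NA_real_
  cap_final <- if (any(pol)) caps[which(pol)[sum(pol)]] else NA_real_
  structure(list(outcomes = outcomes, r_c = r_c, monotone = monotone,
                 cap_area_final = cap_final,
                 cap_area_predicted = if (pred$possible)
                   pred$fraction * sum(mesh$areas) else NA_real_,
                 mesh_cell_area = mean(mesh$areas),
                 prediction = pred, mesh = mesh, config = config,
                 seed = seed),
            class = "epithelial_report")
}

#' @export
print.epithelial_report <- function(x, ...) {
  cat(sprintf("epithelial germ sweep: r_c = %.3g um (%s), final cap %.4g um^2 vs predicted %.4g um^2 (cell %.3g um^2)\n",
              x$r_c, if (x$monotone) "monotone" else "NON-MONOTONE",
              x$cap_area_final, x$cap_area_predicted, x$mesh_cell_area))
  print(x$outcomes, row.names = FALSE)
  invisible(x)
}

#' Run the budding-yeast scenario
#'
#' Stochastic (Gillespie) simulations across a ladder of total amounts of
#' the activating enzyme (the Cdc24-like GEF), mimicking the
#' low-copy-number limit: at small totals the effective potential has a
#' single well and polarization is intermittent ("flickering") - patches
#' of activated Cdc42-like molecules form and dissolve; at large totals
#' in the bistable regime a single persistent patch survives.  The
#' deactivating-enzyme dissociation rate is pre-solved so that the
#' requested fraction of activating enzyme is membrane bound at the
#' reference state (see `bound_frac` in the preset).
#'
#' @param config a preset from [load_preset()] (`"yeast"`).
#' @param seed integer seed.
#' @return object of class `yeast_report`: per-ladder-level list with
#'   `A_tot`, intermittency metrics, `classification`
#'   (`"flickering"`/`"persistent"`/`"ambiguous"`), normalized
#'   cross-section kymograph; plus `config`, `seed`.
#' @export
run_yeast <- function(config, seed = 1L) {
  stopifnot(config$scenario$engine == "ssa")
  p0 <- config$params
  sc <- config$scenario
  mesh <- build_sphere_mesh(sc$mesh_level, R = p0$R)
  lat <- build_lattice(mesh)
  run_one <- function(p, germ) {
    p$k_off_AX <- calibrate_bound_fraction(p, phi_ref = sc$phi_ref,
                                           target = sc$bound_frac)
    phi0 <- rep(sc$phi_init, lat$n_sites)
    if (germ) {
      # heterogeneous germ at the incipient bud site
      cosd <- pmin(pmax(mesh$vertices %*% c(0, 0, 1) / mesh$R, -1), 1)
      phi0[mesh$R * acos(cosd) <= sc$germ_radius] <- 0.95
    }
    st <- lattice_state(lat, p, phi = phi0)
    tr <- gillespie_run(st, sc$t_end, p, lat, seed = seed,
                        snapshot_times = seq(0, sc$t_end,
                                             by = sc$snapshot_dt))
    im <- intermittency_metrics(tr, lat, threshold = sc$patch_threshold,
                                min_nodes = sc$min_flicker_nodes)
    im_cap <- intermittency_metrics(tr, lat,
                                    threshold = sc$patch_threshold,
                                    min_nodes = sc$min_cap_nodes)
    cls <- classify_intermittency(im$n_patches, im_cap$n_patches,
                                  tr$times)
    # cross-section kymograph normalized by the mean membrane level
    path <- mesh$equator
    kym <- t(vapply(seq_along(tr$times), function(i) {
      xs <- tr$counts[i, , "XS"] / lat$areas
      xs[path] / max(mean(xs), 1e-12)
    }, numeric(length(path))))
    rownames(kym) <- signif(tr$times, 8)
    list(A_tot = p$A_tot, metrics = im, cap_metrics = im_cap,
         classification = cls, kymograph = kym, absorbed = tr$absorbed)
  }
  # low-copy ladder (Altschuler-type limit: slow-cycling feedback arm,
  # large catalytic burst per binding, weak deactivating reservoir)
  levels <- lapply(c(sc$A_low, sc$A_mid, sc$A_high), function(A) {
    p <- p0
    p$A_tot <- A
    p$k_cat_A <- p$k_cat_B <- sc$kcat_ladder
    p$k_on_X <- sc$k_on_X_ladder
    p$B_tot <- sc$B_ladder
    run_one(p, germ = FALSE)
  })
  persistent <- run_one(p0, germ = TRUE)
  structure(list(levels = levels, persistent = persistent,
                 config = config, seed = seed),
            class = "yeast_report")
}

# flickering: nanocluster count (single-site scale) returns to zero at
# least twice after clusters first appear; persistent: exactly one
# cap-scale patch in every snapshot of the final half of the run
classify_intermittency <- function(n_flicker, n_cap, times) {
  half <- times >= (min(times) + max(times)) / 2
  persistent <- all(n_cap[half] == 1L)
  first <- which(n_flicker > 0)[1]
  zero_returns <- if (is.na(first)) 0L else {
    r <- rle(n_flicker[seq(first, length(n_flicker))] == 0L)
    sum(r$values)
  }
  if (persistent) "persistent"
  else if (zero_returns >= 2L) "flickering"
  else "ambiguous"
}

#' @export
print.yeast_report <- function(x, ...) {
  for (lv in c(x$levels, list(x$persistent)))
    cat(sprintf("A_tot = %6g: %s (occupied %.2f, %d tracks%s)\n",
                lv$A_tot, lv$classification,
                lv$metrics$fraction_occupied, nrow(lv$metrics$tracks),
                if (lv$absorbed) ", absorbed" else ""))
  invisible(x)
}

#' Run the Ras-nanodomain scenario
#'
#' Two paired stochastic runs differing only in the total amount of the
#' activating enzyme (the SOS-like GEF): one with the enzyme ratio
#' inside the bistable region (started from a supercritical germ of the
#' Ras-GTP-rich phase) and one outside it.  Outside, activated domains
#' are intermittent nanoclusters - none survives longer than the
#' configured persistence horizon; inside, a stable signaling domain
#' persists to the end of the run.
#'
#' @param config a preset from [load_preset()] (`"ras"`).
#' @param seed integer seed.
#' @return object of class `ras_report` with `inside` and `outside`
#'   sub-reports (metrics, classification, longest lifetime), the
#'   `persistence_horizon`, `config`, `seed`.
#' @export
run_ras <- function(config, seed = 1L) {
  stopifnot(config$scenario$engine == "ssa")
  p0 <- config$params
  sc <- config$scenario
  mesh <- build_sphere_mesh(sc$mesh_level, R = p0$R)
  lat <- build_lattice(mesh)
  one <- function(A_tot, germ) {
    p <- p0; p$A_tot <- A_tot
    phi0 <- rep(sc$phi_init, lat$n_sites)
    if (germ) {
      cosd <- pmin(pmax(mesh$vertices %*% c(0, 0, 1) / mesh$R, -1), 1)
      phi0[mesh$R * acos(cosd) <= sc$germ_radius] <- 0.95
    }
    st <- lattice_state(lat, p, phi = phi0)
    tr <- gillespie_run(st, sc$t_end, p, lat, seed = seed,
                        snapshot_times = seq(0, sc$t_end,
                                             by = sc$snapshot_dt))
    im <- intermittency_metrics(tr, lat, threshold = sc$patch_threshold,
                                min_nodes = sc$min_patch_nodes)
    longest <- if (nrow(im$tracks)) max(im$tracks$lifetime) else 0
    ends_with_patch <- tail(im$n_patches, 1) >= 1L
    list(A_tot = A_tot, metrics = im, longest_lifetime = longest,
         ends_with_patch = ends_with_patch, absorbed = tr$absorbed)
  }
  inside <- one(sc$A_inside, germ = TRUE)
  outside <- one(sc$A_outside, germ = FALSE)
  structure(list(inside = inside, outside = outside,
                 persistence_horizon = sc$persistence_horizon,
                 config = config, seed = seed),
            class = "ras_report")
}

#' @export
print.ras_report <- function(x, ...) {
  cat(sprintf("Ras domains: inside-bistable longest lifetime %.4g s (ends with patch: %s); outside longest %.4g s (horizon %.4g s)\n",
              x$inside$longest_lifetime, x$inside$ends_with_patch,
              x$outside$longest_lifetime, x$persistence_horizon))
  invisible(x)
}

#' Pre-solve the feedback-arm dissociation rate for a bound fraction
#'
#' Adjusts `k_off_AX` so that at the uniform reference state with
#' activated fraction `phi_ref` (and the preset's receptor level) the
#' requested fraction of the activating enzyme is membrane bound.
#' Used by the yeast preset ("10% of A molecules bound").
#'
#' @param params a [polarity_params()] object.
#' @param phi_ref reference activated fraction.
#' @param target target bound fraction in (0, 1).
#' @return the calibrated `k_off_AX` (1/s).
#' @export
calibrate_bound_fraction <- function(params, phi_ref, target = 0.1) {
  stopifnot(target > 0, target < 1)
  rho_R <- receptor_density(params$signal, 0)
  # bound fraction = load / (1 + load), load = (ktilR*rhoR + ktilX*x*) S/V
  load_target <- target / (1 - target)
  load_R <- ktil_R(params) * rho_R * params$S_area / params$V_cyt
  load_X_needed <- load_target - load_R
  if (load_X_needed <= 0)
    stop("receptor binding alone exceeds the target bound fraction")
  ktilX_needed <- load_X_needed * params$V_cyt /
    (phi_ref * params$X_tot * params$S_area)
  params$k_on_X / ktilX_needed
}
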
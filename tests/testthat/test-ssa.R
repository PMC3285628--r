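test_that("the lattice mirrors the mesh combinatorics", {
  mesh <- get_mesh(0, R = 5)
  lat <- build_lattice(mesh)
  expect_equal(lat$n_sites, 12)
  expect_true(all(lengths(lat$neighbors) == 5))
  # neighbour relation symmetric
  for (i in seq_len(lat$n_sites))
    for (j in lat$neighbors[[i]])
      expect_true(i %in% lat$neighbors[[j]])
  expect_equal(lat$S_area, sum(mesh$areas))
})

test_that("propensities vanish on empty sites and reservoirs", {
  p <- default_params()
  lat <- build_lattice(get_mesh(0, R = 5))
  st <- lattice_state(lat, p, phi = 0.2)
  st$counts[1, ] <- 0L
  st$A_cyt <- 0; st$B_cyt <- 0
  pr <- compute_propensities(st, p, lat)
  expect_equal(unname(pr$reaction[1, ]), rep(0, 8))
  expect_equal(unname(pr$diffusion[1, ]), rep(0, 2))
  # binding everywhere is off with empty reservoirs
  expect_equal(sum(pr$reaction[, c("bind_AR", "bind_AX", "bind_B")]), 0)
  st2 <- st; st2$counts[2, 1] <- -1L
  expect_error(compute_propensities(st2, p, lat), "negative")
})

test_that("the Gillespie core is deterministic under a seed and conserves totals", {
  p <- polarity_params(R = 2.5, X_tot = 200, K_A = 20, K_B = 20,
                       A_tot = 5000, B_tot = 5000)
  lat <- build_lattice(get_mesh(2, R = 2.5))
  st <- lattice_state(lat, p, phi = 0.3)
  tr1 <- gillespie_run(st, 10, p, lat, seed = 7)
  tr2 <- gillespie_run(st, 10, p, lat, seed = 7)
  expect_identical(tr1$counts, tr2$counts)
  expect_identical(tr1$n_events, tr2$n_events)
  expect_gt(tr1$n_events, 1e5)
  # conservation after every event is equivalent to conservation of the
  # final state given the per-event bookkeeping; check all three budgets
  fc <- tr1$final$counts
  expect_equal(sum(fc[, c("XS", "X0")]), sum(st$counts[, c("XS", "X0")]))
  expect_equal(sum(fc[, c("AR", "AX")]) + tr1$final$A_cyt, p$A_tot)
  expect_equal(sum(fc[, "B"]) + tr1$final$B_cyt, p$B_tot)
  # intermediate snapshots conserve too
  for (i in c(25, 50, 100)) {
    expect_equal(sum(tr1$counts[i, , c("XS", "X0")]),
                 sum(st$counts[, c("XS", "X0")]))
    expect_equal(sum(tr1$counts[i, , c("AR", "AX")]) +
                   tr1$reservoirs[i, 1], p$A_tot)
  }
})

test_that("pure diffusion relaxes to the uniform occupancy distribution", {
  # all reactions off: symmetric random walk on 12 equal-area sites
  p <- polarity_params(R = 5, k_cat_A = 0, k_cat_B = 0, k_on_R = 0,
                       k_on_X = 0, k_on_B = 0, k_off_AR = 0,
                       k_off_AX = 0, k_off_B = 0, X_tot = 40, D = 0.5)
  lat <- build_lattice(get_mesh(0, R = 5))
  # start with everything on one site
  st <- lattice_state(lat, p, phi = 0.5)
  tot <- sum(st$counts[, "XS"])
  st$counts[, "XS"] <- 0L; st$counts[1, "XS"] <- as.integer(tot)
  # a single late snapshot: the walkers are independent, so the site
  # occupancy at one well-mixed time is multinomial
  tr <- gillespie_run(st, 2000, p, lat, seed = 3,
                      snapshot_times = c(2000))
  final <- tr$counts[1, , "XS"]
  expect_gt(stats::chisq.test(final)$p.value, 0.01)
})

test_that("a large-count single site fluctuates about the deterministic root", {
  # monostable-low regime with an interior root, so the lipid field
  # genuinely fluctuates about the mean-field equilibrium
  p <- polarity_params(R = 1.3, X_tot = 4000, K_A = 400, K_B = 400,
                       A_tot = 3000, B_tot = 30000, k_cat_A = 1,
                       k_cat_B = 1)
  p$signal <- signal_schedule("constant",
                              rho_R = receptor_from_sigma(0.3, p))
  mesh0 <- get_mesh(0, R = 1.3)
  lat <- build_lattice(mesh0)
  lat$n_sites <- 1L
  lat$areas <- sum(mesh0$areas)
  lat$neighbors <- list(integer(0))
  lat$nbr <- integer(0); lat$nbr_ptr <- c(0L, 0L)
  lat$S_area <- sum(mesh0$areas)
  p_lat <- p; p_lat$S_area <- lat$S_area
  p_lat$chi <- p_lat$S_area / p_lat$V_cyt
  ss <- uniform_steady_state(p_lat, rho_R = p$signal$rho_R,
                             phi0 = 0, branch = "low")
  st <- lattice_state(lat, p, phi = ss$phi, receptor = p$signal$rho_R)
  pr <- compute_propensities(st, p, lat)
  expect_equal(unname(pr$diffusion), matrix(0, 1, 2),
               ignore_attr = TRUE)
  tr <- gillespie_run(st, 400, p, lat, seed = 5,
                      snapshot_times = seq(100, 400, by = 10))
  phis <- tr$counts[, 1, "XS"] / (tr$counts[, 1, "XS"] +
                                    tr$counts[, 1, "X0"])
  m <- mean(phis)
  # standard error with a crude effective sample size from lag-1
  # autocorrelation of the thinned series
  r1 <- stats::cor(phis[-1], phis[-length(phis)])
  neff <- length(phis) * (1 - r1) / (1 + r1)
  se <- stats::sd(phis) / sqrt(max(neff, 4))
  expect_lt(abs(m - ss$phi), 3 * se + 2e-3)
})

test_that("a two-state binding cycle matches its binomial stationary law", {
  # freeze everything except B binding/unbinding on a single site:
  # each of the B_tot molecules independently binds at rate
  # k_on_B * X0 / V and unbinds at k_off_B -> binomial occupancy
  p <- polarity_params(R = 1.3, X_tot = 500, k_cat_A = 0, k_cat_B = 0,
                       k_on_R = 0, k_on_X = 0, k_on_B = 0.02,
                       k_off_AR = 1, k_off_AX = 1, k_off_B = 0.5,
                       A_tot = 0, B_tot = 60)
  mesh0 <- get_mesh(0, R = 1.3)
  lat <- build_lattice(mesh0)
  lat$n_sites <- 1L; lat$areas <- sum(mesh0$areas)
  lat$neighbors <- list(integer(0))
  lat$nbr <- integer(0); lat$nbr_ptr <- c(0L, 0L)
  lat$S_area <- sum(mesh0$areas)
  st <- lattice_state(lat, p, phi = 0)
  X0 <- st$counts[1, "X0"]
  rate_on <- p$k_on_B * X0 / p$V_cyt
  pbind <- rate_on / (rate_on + p$k_off_B)
  tr <- gillespie_run(st, 6000, p, lat, seed = 9,
                      snapshot_times = seq(20, 6000, by = 0.06))
  occ <- tr$counts[, 1, "B"]
  emp <- tabulate(occ + 1L, nbins = p$B_tot + 1) / length(occ)
  theo <- stats::dbinom(0:p$B_tot, p$B_tot, pbind)
  tv <- 0.5 * sum(abs(emp - theo))
  expect_gt(length(occ), 1e4)
  expect_lt(tv, 0.02)
})

test_that("intermittency metrics handle empty and persistent trajectories", {
  p <- polarity_params(R = 2.5, X_tot = 200, K_A = 20, K_B = 20,
                       A_tot = 2000, B_tot = 2000)
  lat <- build_lattice(get_mesh(1, R = 2.5))
  # all-zero activity
  st0 <- lattice_state(lat, p, phi = 0)
  arr <- array(0L, dim = c(3, lat$n_sites, 5),
               dimnames = list(NULL, NULL, colnames(st0$counts)))
  for (i in 1:3) arr[i, , ] <- st0$counts
  quiet <- structure(list(times = c(0, 1, 2), counts = arr),
                     class = "ssa_trajectory")
  im0 <- intermittency_metrics(quiet, lat, threshold = 0.5)
  expect_equal(nrow(im0$tracks), 0)
  expect_equal(im0$fraction_occupied, 0)
  # one persistent cap spanning the whole window
  cosd <- pmin(pmax(lat$mesh$vertices %*% c(0, 0, 1) / 2.5, -1), 1)
  phi <- ifelse(2.5 * acos(cosd) <= 1, 0.95, 0.02)
  stc <- lattice_state(lat, p, phi = phi)
  pers <- quiet
  for (i in 1:3) pers$counts[i, , ] <- stc$counts
  im1 <- intermittency_metrics(pers, lat, threshold = 0.5)
  expect_equal(nrow(im1$tracks), 1)
  expect_equal(im1$tracks$lifetime, 2)
  expect_equal(im1$fraction_occupied, 1)
})
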
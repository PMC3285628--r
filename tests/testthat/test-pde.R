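test_that("a consistent uniform equilibrium is a fixed point of the RHS", {
  p <- default_params()
  mesh <- get_mesh(2, R = 5)
  ss <- uniform_steady_state(p, rho_R = 0, branch = "low")
  st <- initial_state(mesh, p, phi = ss$phi)
  r <- assemble_rhs(st, 0, p, mesh)
  expect_lt(max(abs(unlist(r))), 1e-9)
})

test_that("the RHS conserves lipid pointwise totals and enzyme budgets", {
  p <- default_params()
  p$signal <- signal_schedule("constant", rho_R = 15)
  mesh <- get_mesh(2, R = 5)
  set.seed(8)
  st <- initial_state(mesh, p, phi = 0.3, noise_rel = 0.1)
  r <- assemble_rhs(st, 0, p, mesh)
  # diffusion rows sum to zero and the conversion flux cancels pairwise
  expect_lt(abs(sum(mesh$areas * (r$dx_star + r$dx_0))), 1e-9)
  # reservoir derivative equals minus the surface integral of net
  # binding, recomputed here by independent quadrature
  cA <- st$A_cyt / p$V_cyt
  netA <- p$k_on_R * 15 * cA + p$k_on_X * st$x_star * cA -
    p$k_off_AR * st$a_R - p$k_off_AX * st$a_X
  expect_equal(r$dA_cyt, -sum(mesh$areas * netA), tolerance = 1e-12)
  stm <- st; stm$x_star[1] <- NaN
  expect_error(assemble_rhs(stm, 0, p, mesh), "invalid state")
})

test_that("monostable dynamics converge uniformly to the unique root", {
  p <- polarity_params(B_tot = 2000)   # weak deactivating arm
  mesh <- get_mesh(2, R = 5)
  set.seed(2)
  st <- initial_state(mesh, p, phi = 0.3, noise_rel = 0.05)
  tr <- simulate_meanfield(st, 250, p, mesh, times = c(0, 250),
                           rtol = 1e-6)
  stf <- tr$snapshots[[2]]
  rc <- reduced_coordinates(stf$A_cyt, stf$B_cyt, 0, p)
  eq <- find_equilibria(rc$rho, rc$sigma, p)
  root <- max(eq$phi[eq$stable])
  expect_lt(max(abs(stf$x_star / p$X_tot - root)), 1e-4)
})

test_that("identical seed and configuration reproduce the trajectory bitwise", {
  p <- default_params()
  mesh <- get_mesh(1, R = 5)
  st <- initial_state(mesh, p, phi = 0.02)
  nz <- noise_config(rate = 1, action = "set_phi", phi_set = 1)
  t1 <- simulate_meanfield(st, 10, p, mesh, times = c(0, 5, 10),
                           noise = nz, seed = 99, rtol = 1e-5)
  t2 <- simulate_meanfield(st, 10, p, mesh, times = c(0, 5, 10),
                           noise = nz, seed = 99, rtol = 1e-5)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$events, t2$events)
})

test_that("lipid and enzyme totals are conserved over a full run", {
  p <- default_params()
  p$signal <- signal_schedule("step", rho_R = 30, t_on = 1)
  mesh <- get_mesh(2, R = 5)
  set.seed(4)
  st <- initial_state(mesh, p, phi = 0.1, noise_rel = 0.05)
  tr <- simulate_meanfield(st, 60, p, mesh, times = c(0, 60), rtol = 1e-6)
  stf <- tr$snapshots[[2]]
  tot0 <- sum(mesh$areas * (st$x_star + st$x_0))
  totf <- sum(mesh$areas * (stf$x_star + stf$x_0))
  expect_lt(abs(totf - tot0) / tot0, 1e-6)
  expect_lt(abs(sum(mesh$areas * (stf$a_R + stf$a_X)) + stf$A_cyt -
                  p$A_tot) / p$A_tot, 1e-6)
  expect_lt(abs(sum(mesh$areas * stf$b) + stf$B_cyt - p$B_tot) /
              p$B_tot, 1e-6)
  # pointwise lipid total intact
  expect_equal(stf$x_star + stf$x_0, rep(p$X_tot, length(stf$x_star)))
})

test_that("noise off leaves the state untouched; events arrive as a Poisson process", {
  p <- default_params()
  mesh <- get_mesh(0, R = 5)
  ss <- uniform_steady_state(p, rho_R = 0, branch = "low")
  st <- initial_state(mesh, p, phi = ss$phi)
  tr0 <- simulate_meanfield(st, 20, p, mesh, times = c(0, 20),
                            noise = noise_config(rate = 0), seed = 1)
  expect_equal(nrow(tr0$events), 0)
  expect_equal(tr0$snapshots[[2]]$x_star, st$x_star, tolerance = 1e-9)
  # event counts across independent runs: mean within 3 sd(mean) of
  # lambda * T
  lam <- 1.5; T <- 8
  nz <- noise_config(rate = lam, action = "gaussian", amplitude = 0.01)
  counts <- vapply(1:100, function(s) {
    tr <- simulate_meanfield(st, T, p, mesh, times = c(0, T), noise = nz,
                             seed = s, rtol = 1e-4)
    nrow(tr$events)
  }, numeric(1))
  expect_lt(abs(mean(counts) - lam * T), 3 * sqrt(lam * T / 100))
  # index-two moment consistent with Poisson dispersion (generous band)
  expect_gt(var(counts) / mean(counts), 0.5)
  expect_lt(var(counts) / mean(counts), 2.0)
})

test_that("noise events pick nodes uniformly", {
  p <- default_params()
  mesh <- get_mesh(0, R = 5)
  ss <- uniform_steady_state(p, rho_R = 0, branch = "low")
  st <- initial_state(mesh, p, phi = ss$phi)
  nz <- noise_config(rate = 200, action = "gaussian", amplitude = 0)
  tr <- simulate_meanfield(st, 30, p, mesh, times = c(0, 30), noise = nz,
                           seed = 12, rtol = 1e-4)
  tab <- tabulate(tr$events$node, nbins = 12)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("kymographs report the perimeter band geometry", {
  p <- default_params()
  mesh <- get_mesh(3, R = 5)
  st <- initial_state(mesh, p, phi = 0.25)
  tr <- list(times = 0, snapshots = list(st))
  class(tr) <- "polarity_trajectory"
  km <- kymograph(tr, mesh)
  expect_equal(ncol(km), length(mesh$equator))
  expect_equal(unname(km[1, ]), rep(0.25, ncol(km)), tolerance = 1e-12)
  # a polar cap centred ON the sampled circle covers an angular band of
  # width 2 theta
  theta <- pi / 5
  ctr <- mesh$vertices[mesh$equator[1], ] / 5
  cosd <- pmin(pmax(mesh$vertices %*% ctr / 5, -1), 1)
  phi <- ifelse(acos(cosd) <= theta, 0.9, 0.1)
  st2 <- initial_state(mesh, p, phi = phi)
  km2 <- kymograph(list(times = 0, snapshots = list(st2)), mesh)
  frac_hot <- mean(km2[1, ] > 0.5)
  spacing <- 2 * pi / ncol(km2)
  expect_lt(abs(frac_hot - 2 * theta / (2 * pi)), 2.5 * spacing / (2 * pi) + 0.02)
})

test_that("patch detection matches cap geometry and a graph-components oracle", {
  mesh <- get_mesh(3, R = 5)
  # all below threshold
  expect_equal(nrow(detect_patches(rep(0.1, nrow(mesh$vertices)), mesh,
                                   threshold = 0.5)), 0)
  # single cap: area within the boundary-band bound (about half a node
  # ring along the cap perimeter)
  theta <- pi / 3
  cosd <- pmin(pmax(mesh$vertices[, 3] / 5, -1), 1)
  phi <- ifelse(acos(cosd) <= theta, 1, 0)
  pa <- detect_patches(phi, mesh, threshold = 0.5)
  expect_equal(nrow(pa), 1)
  exact <- 2 * pi * 25 * (1 - cos(theta))
  h <- sqrt(mean(mesh$areas))
  expect_lt(abs(pa$area[1] - exact), 0.5 * 2 * pi * 5 * sin(theta) * h)
  # two antipodal caps against an independent flood-fill (igraph)
  phi2 <- ifelse(pmin(acos(cosd), pi - acos(cosd)) <= pi / 6, 1, 0)
  pa2 <- detect_patches(phi2, mesh, threshold = 0.5)
  expect_equal(nrow(pa2), 2)
  above <- which(phi2 > 0.5)
  edges <- do.call(rbind, lapply(above, function(i) {
    nb <- intersect(mesh$neighbors[[i]], above)
    if (length(nb)) cbind(i, nb) else NULL
  }))
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = FALSE)
  comp <- igraph::components(g)
  expect_equal(comp$no, nrow(pa2))
  sizes <- sort(as.integer(comp$csize))
  expect_equal(sizes, sort(pa2$n_nodes))
})

test_that("the discrete effective functional descends with frozen reservoirs", {
  # effectively infinite reservoirs freeze the reduced coordinates
  scale <- 1e4
  p <- polarity_params(A_tot = 6e4 * scale, B_tot = 6e4 * scale,
                       V_cyt = 4 / 3 * pi * 125 * scale,
                       k_cat_A = 1, k_cat_B = 1)
  mesh <- get_mesh(2, R = 5)
  rc <- reduced_coordinates(p$A_tot, p$B_tot, 0, p)
  set.seed(21)
  st <- initial_state(mesh, p, phi = pmin(pmax(
    0.5 + 0.45 * sin(2 * mesh$vertices[, 3]) +
      0.05 * rnorm(nrow(mesh$vertices)), 0), 1))
  times <- seq(0, 40, by = 5)
  tr <- simulate_meanfield(st, 40, p, mesh, times = times, rtol = 1e-7)
  tab <- effective_potential(seq(0, 1, length.out = 1001), rc$rho,
                             rc$sigma, p, rate_scale = rc$gamma)
  Vfun <- stats::splinefun(tab$phi, tab$V, method = "natural")
  E <- vapply(tr$snapshots, function(s)
    effective_energy(s$x_star / p$X_tot, mesh, rc$rho, rc$sigma, p,
                     V_interp = Vfun), numeric(1))
  expect_true(all(diff(E) < 1e-6 * abs(E[1]) + 1e-10))
})

test_that("fronts are stationary on the coexistence line and follow delta V", {
  p <- default_params()
  cl <- coexistence_line(0.05, p)
  fv <- front_velocity_1d(cl$rho_star, 0.05, p, domain_length = 30,
                          resolution = 512, t_settle = 30, t_measure = 60)
  expect_lt(abs(fv$v), 1e-3 * sqrt(p$D * p$k_cat_A))
  up <- front_velocity_1d(cl$rho_star * 1.02, 0.05, p, domain_length = 30,
                          resolution = 512, t_settle = 30, t_measure = 60)
  dn <- front_velocity_1d(cl$rho_star * 0.98, 0.05, p, domain_length = 30,
                          resolution = 512, t_settle = 30, t_measure = 60)
  expect_gt(up$v, 0)   # activating arm strengthened: activated phase advances
  expect_lt(dn$v, 0)
})

test_that("VTK and CSV exports write well-formed text files", {
  mesh <- get_mesh(0)
  f <- tempfile(fileext = ".vtk")
  write_vtk(mesh, list(phi = runif(12)), f)
  lines <- readLines(f)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS 12 double$", lines)))
  expect_true(any(grepl("^POLYGONS 20 80$", lines)))
  expect_true(any(grepl("^SCALARS phi double 1$", lines)))
  km <- matrix(1:6, 2, 3, dimnames = list(c("0", "1"), c("a", "b", "c")))
  fk <- tempfile(fileext = ".csv")
  write_kymograph_csv(km, fk)
  back <- utils::read.csv(fk, check.names = FALSE)
  expect_equal(dim(back), c(2, 4))
})

test_that("a larger patch grows at the expense of a smaller one until one survives", {
  cfg <- load_preset("epithelial")
  p <- cfg$params
  mesh <- get_mesh(3, R = 5)
  hi <- uniform_steady_state(p, rho_R = p$signal$rho_R, phi0 = 1,
                             branch = "high")
  pred <- patch_area_ratio(p, sigma_from_receptor(p$signal$rho_R, p))
  st <- initial_state(mesh, p, phi = hi$phi)
  for (g in list(list(c(0, 0, 1), 1.4), list(c(0, 0, -1), 0.95))) {
    cosd <- pmin(pmax(mesh$vertices %*% g[[1]] / 5, -1), 1)
    idx <- which(5 * acos(cosd) <= g[[2]])
    st$x_star[idx] <- pred$phi_minus * p$X_tot
    st$x_0[idx] <- p$X_tot - st$x_star[idx]
  }
  eqz <- enzyme_equilibria(st$x_star, st$x_0, p$signal$rho_R, p,
                           weights = mesh$areas)
  st$a_R <- eqz$a_R; st$a_X <- eqz$a_X; st$b <- eqz$b
  st$A_cyt <- eqz$A_cyt; st$B_cyt <- eqz$B_cyt
  tms <- seq(0, 500, by = 25)
  tr <- simulate_meanfield(st, 500, p, mesh, times = tms, rtol = 1e-5)
  small_area <- vapply(seq_along(tr$times), function(i) {
    s <- tr$snapshots[[i]]
    pa <- detect_patches(1 - s$x_star / p$X_tot, mesh, threshold = 0.7)
    pa <- pa[pa$n_nodes >= 2, , drop = FALSE]
    if (nrow(pa) >= 2) pa$area[2] else 0
  }, numeric(1))
  n_final <- {
    s <- tr$snapshots[[length(tr$times)]]
    pa <- detect_patches(1 - s$x_star / p$X_tot, mesh, threshold = 0.7)
    nrow(pa[pa$n_nodes >= 2, , drop = FALSE])
  }
  expect_equal(n_final, 1L)
  # after the reservoir tightens, the smaller patch only shrinks
  ipk <- which.max(small_area)
  expect_true(all(diff(small_area[ipk:length(small_area)]) <= 1e-9))
  expect_gt(small_area[ipk], 0)
})

test_that("the polarized cap area converges under mesh refinement", {
  # one refinement pair of the production ladder, compared through the
  # reservoir-consistent moment measure of the cap
  cfg <- load_preset("epithelial")
  p <- cfg$params
  caps <- vapply(c(3L, 4L), function(lev) {
    mesh <- get_mesh(lev, R = 5)
    hi <- uniform_steady_state(p, rho_R = p$signal$rho_R, phi0 = 1,
                               branch = "high")
    st <- initial_state(mesh, p, phi = hi$phi,
                        germ = list(center = c(0, 0, 1), radius = 1.2,
                                    phi_in = 0.005))
    tr <- simulate_meanfield(st, 700, p, mesh, times = c(0, 700),
                             rtol = 1e-5)
    stf <- tr$snapshots[[2]]
    frac <- polarisim:::cap_area_moment(stf, mesh, p) / sum(mesh$areas)
    frac
  }, numeric(1))
  expect_lt(abs(caps[2] - caps[1]) / caps[1], 0.02)
})
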
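test_that("conversion flux obeys its limiting forms", {
  p <- default_params()
  # no enzyme, no flux
  expect_equal(conversion_flux(300, 300, 0, 0, 0, p), 0)
  # symmetric parameters, balanced enzymes, balanced substrate
  ps <- symmetric_params()
  expect_equal(conversion_flux(300, 300, 2, 3, 5, ps), 0, tolerance = 1e-14)
  # zero-order ultrasensitive limit: K << densities -> saturated rates
  pz <- polarity_params(K_A = 1e-6 * 600, K_B = 1e-6 * 600)
  F <- conversion_flux(250, 350, 4, 6, 7, pz)
  F_lim <- pz$k_cat_A * (4 + 6) - pz$k_cat_B * 7
  expect_lt(abs(F - F_lim) / abs(F_lim), 1e-3)
  expect_error(conversion_flux(-1, 300, 0, 0, 0, p), "negative")
})

test_that("enzyme equilibria conserve totals exactly and slave to recruiters", {
  p <- default_params()
  mesh <- get_mesh(2, R = 5)
  n <- nrow(mesh$vertices)
  # zero recruiters -> all A free
  eq0 <- enzyme_equilibria(rep(0, n), rep(p$X_tot, n), 0, p,
                           weights = mesh$areas)
  expect_equal(eq0$a_R, rep(0, n))
  expect_equal(eq0$a_X, rep(0, n))
  expect_equal(eq0$A_cyt, p$A_tot)
  # arbitrary smooth fields: conservation to 1e-12 relative
  set.seed(5)
  phi <- 0.4 + 0.3 * sin(mesh$vertices[, 3])
  rec <- 20 * (1 + mesh$vertices[, 1] / p$R)
  eq <- enzyme_equilibria(phi * p$X_tot, (1 - phi) * p$X_tot, rec, p,
                          weights = mesh$areas)
  boundA <- sum(mesh$areas * (eq$a_R + eq$a_X))
  boundB <- sum(mesh$areas * eq$b)
  expect_lt(abs(boundA + eq$A_cyt - p$A_tot) / p$A_tot, 1e-12)
  expect_lt(abs(boundB + eq$B_cyt - p$B_tot) / p$B_tot, 1e-12)
  # proportionality to recruiters at fixed free concentration
  expect_equal(eq$a_X / (phi * p$X_tot),
               rep((p$k_on_X / p$k_off_AX) * eq$A_cyt / p$V_cyt, n))
})

test_that("enzyme equilibria match long-time integration of the shuttling ODEs", {
  p <- default_params()
  mesh <- get_mesh(1, R = 5)
  n <- nrow(mesh$vertices)
  set.seed(11)
  phi <- runif(n, 0.1, 0.9)
  rec <- runif(n, 0, 30)
  w <- mesh$areas
  eq <- enzyme_equilibria(phi * p$X_tot, (1 - phi) * p$X_tot, rec, p,
                          weights = w)
  # independent route: integrate the raw binding/unbinding ODE system at
  # frozen lipid fields until stationary
  rhs <- function(t, y, parms) {
    aR <- y[1:n]; aX <- y[n + 1:n]; b <- y[2 * n + 1:n]
    A_cyt <- p$A_tot - sum(w * (aR + aX))
    B_cyt <- p$B_tot - sum(w * b)
    cA <- A_cyt / p$V_cyt; cB <- B_cyt / p$V_cyt
    list(c(p$k_on_R * rec * cA - p$k_off_AR * aR,
           p$k_on_X * phi * p$X_tot * cA - p$k_off_AX * aX,
           p$k_on_B * (1 - phi) * p$X_tot * cB - p$k_off_B * b))
  }
  out <- deSolve::lsoda(rep(0, 3 * n), c(0, 500 / p$k_off_AX), rhs,
                        parms = NULL, rtol = 1e-12, atol = 1e-12)
  fin <- out[2, -1]
  expect_lt(max(abs(fin[1:n] - eq$a_R)) / max(eq$a_R), 1e-6)
  expect_lt(max(abs(fin[n + 1:n] - eq$a_X)) / max(eq$a_X), 1e-6)
  expect_lt(max(abs(fin[2 * n + 1:n] - eq$b)) / max(eq$b), 1e-6)
})

test_that("reduced reaction vanishes at its roots and has the bistable sign pattern", {
  p <- default_params()
  rho <- 2; sigma <- 0.05
  eq <- find_equilibria(rho, sigma, p)
  expect_true(all(abs(reduced_reaction(eq$phi, rho, sigma, p)) < 1e-10))
  # sign pattern between the three roots, dense scan
  stopifnot(nrow(eq) == 3)
  r <- eq$phi
  u <- seq(r[1] + 1e-6, r[2] - 1e-6, length.out = 5000)
  expect_true(all(reduced_reaction(u, rho, sigma, p) < 0))
  u <- seq(r[2] + 1e-6, r[3] - 1e-6, length.out = 5000)
  expect_true(all(reduced_reaction(u, rho, sigma, p) > 0))
  expect_error(reduced_reaction(0.5, -1, 0, p), "rho")
})

test_that("symmetric pathway gives an odd reaction term about one half", {
  p <- symmetric_params()
  phi <- seq(0, 1, length.out = 301)
  f1 <- reduced_reaction(phi, 1, 0, p)
  f2 <- reduced_reaction(1 - phi, 1, 0, p)
  expect_equal(f1, -f2, tolerance = 1e-13)
  expect_equal(reduced_reaction(0.5, 1, 0, p), 0)
})

test_that("effective potential is the antiderivative of -f", {
  set.seed(42)
  for (k in 1:10) {
    p <- polarity_params(K_A = runif(1, 20, 120), K_B = runif(1, 20, 120))
    rho <- exp(runif(1, -1, 1)); sigma <- runif(1, 0, 0.3)
    grid <- seq(0, 1, length.out = 201)
    V <- effective_potential(grid, rho, sigma, p)
    expect_equal(V$V[1], 0)
    h <- grid[2] - grid[1]
    dV <- (V$V[3:201] - V$V[1:199]) / (2 * h)
    f_mid <- reduced_reaction(grid[2:200], rho, sigma, p)
    # central differences match -f up to the quadrature tolerance plus
    # the unavoidable O(h^2) finite-difference truncation term
    fpp <- max(abs(diff(reduced_reaction(grid, rho, sigma, p),
                        differences = 2))) / h^2
    expect_lt(max(abs(dV + f_mid)),
              1e-6 * max(abs(f_mid)) + h^2 / 6 * fpp * 1.5 + 1e-10)
  }
})

test_that("potential depths are equal on the coexistence line", {
  p <- default_params()
  cl <- coexistence_line(0.05, p)
  eq <- find_equilibria(cl$rho_star, 0.05, p)
  st <- eq$phi[eq$stable]
  Vv <- effective_potential(sort(st), cl$rho_star, 0.05, p)
  expect_lt(abs(diff(Vv$V)), 1e-8)
})

test_that("quasi-steady-state reduction tracks the full local dynamics", {
  # timescale separation: off rates 100x the catalytic rates; reservoirs
  # effectively infinite so the reduced coordinates stay constant
  scale <- 1e4
  p <- polarity_params(k_cat_A = 0.05, k_cat_B = 0.05,
                       k_on_R = 0.06, k_on_X = 0.06, k_on_B = 0.06,
                       k_off_AR = 5, k_off_AX = 5, k_off_B = 5,
                       A_tot = 6e4 * scale, B_tot = 1.2e5 * scale,
                       V_cyt = 4 / 3 * pi * 125 * scale)
  p$signal <- signal_schedule("constant",
                              rho_R = receptor_from_sigma(0.05, p))
  times <- seq(0, 150, by = 0.5)
  full <- simulate_local(times, p, phi0 = 0.35)
  rc <- reduced_coordinates(full$A_cyt[1], full$B_cyt[1],
                            p$signal$rho_R, p)
  red <- deSolve::lsoda(c(phi = 0.35), times,
                        function(t, y, parms)
                          list(reduced_reaction(y, rc$rho, rc$sigma, p,
                                                rate_scale = rc$gamma)),
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  # compare after the initial boundary layer (a few enzyme lifetimes)
  sel <- times > 5 / p$k_off_AX
  expect_lt(max(abs(full$phi[sel] - red[sel, "phi"])), 0.02)
})
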
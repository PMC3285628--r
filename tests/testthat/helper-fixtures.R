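# shared fixtures: parameter sets and cached meshes

# fully symmetric pathway: equal catalytic arms, equal Michaelis
# constants, equal affinities and totals -> f(phi; 1, 0) is odd about 1/2
symmetric_params <- function(...) {
  polarity_params(k_cat_A = 1, k_cat_B = 1, K_A = 60, K_B = 60,
                  k_on_R = 0.012, k_on_X = 0.012, k_on_B = 0.012,
                  k_off_AR = 1, k_off_AX = 1, k_off_B = 1,
                  A_tot = 60000, B_tot = 60000, X_tot = 600, D = 0.1,
                  R = 5, ...)
}

# default study parameters (asymmetric totals)
default_params <- function(...) polarity_params(...)

# mesh cache (builds are deterministic, reuse across tests)
.mesh_cache <- new.env(parent = emptyenv())
get_mesh <- function(level, R = 1) {
  key <- sprintf("L%d_R%g", level, R)
  m <- .mesh_cache[[key]]
  if (is.null(m)) {
    m <- build_sphere_mesh(level, R = R)
    .mesh_cache[[key]] <- m
  }
  m
}

# independent root finder for the reduced dynamics: the interior
# equilibria solve the quadratic
#   (1+rho) phi^2 + (rho (sigma+kappa_B) - (1+kappa_A)) phi
#     + rho sigma kappa_B = 0
# and phi = 1 is always a root (phi = 0 too when sigma = 0)
quadratic_roots <- function(rho, sigma, params) {
  kA <- params$K_A / params$X_tot
  kB <- params$K_B / params$X_tot
  a <- 1 + rho
  b <- rho * (sigma + kB) - (1 + kA)
  cc <- rho * sigma * kB
  disc <- b^2 - 4 * a * cc
  interior <- if (disc >= 0) {
    r <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    r[r > 1e-14 & r < 1 - 1e-14]
  } else numeric(0)
  sort(unique(c(if (sigma == 0) 0, interior, 1)))
}
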
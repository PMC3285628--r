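#' Chemical equilibria of the reduced dynamics
#'
#' Locates every zero of the reduced reaction term `f(phi; rho, sigma)` in
#' `[0, 1]` and flags its stability.  Interior roots are found by
#' sign-change bracketing on a 2048-interval grid refined by bisection to
#' an absolute tolerance of 1e-12; the structural boundary roots
#' (`phi = 1` always, `phi = 0` when `sigma = 0`) are added explicitly.
#' Stability comes from the sign of `f'` (central finite difference, one
#' sided at the boundaries).
#'
#' @param rho enzyme ratio, `> 0`.
#' @param sigma renormalized activation signal, `>= 0`.
#' @param params a [polarity_params()] object.
#' @param rate_scale optional rate scale for [reduced_reaction()].
#' @return data.frame with columns `phi` (ascending) and `stable`
#'   (logical).  In the bistable regime the three roots are
#'   stable/unstable/stable: the low equilibrium `phi_minus`, the barrier
#'   `phi_u`, and the high equilibrium `phi_plus`.
#' @export
find_equilibria <- function(rho, sigma, params, rate_scale = NULL) {
  f <- function(u) reduced_reaction(u, rho, sigma, params, rate_scale)
  # boundary signs of the reconstruction: f(0) >= 0, f(1) = 0
  stopifnot(f(0) >= -1e-15, abs(f(1)) < 1e-12)
  grid <- seq(0, 1, length.out = 2049L)
  fg <- f(grid)
  roots <- numeric(0)
  if (sigma == 0) roots <- c(roots, 0)
  # interior sign changes (exclude the structural zeros at the endpoints)
  for (i in seq_len(length(grid) - 1L)) {
    a <- grid[i]; b <- grid[i + 1L]
    fa <- fg[i]; fb <- fg[i + 1L]
    if (i == 1L && sigma == 0) next            # endpoint zero, not a crossing
    if (i == length(grid) - 1L) next           # phi = 1 handled explicitly
    if (fa == 0 && a > 0) { roots <- c(roots, a); next }
    if (fa * fb < 0) {
      while (b - a > 1e-12) {
        m <- (a + b) / 2
        fm <- f(m)
        if (fm == 0) { a <- m; b <- m; break }
        if (fa * fm < 0) b <- m else { a <- m; fa <- fm }
      }
      roots <- c(roots, (a + b) / 2)
    }
  }
  roots <- sort(unique(c(roots, 1)))
  h <- 1e-7
  stable <- vapply(roots, function(r) {
    lo <- max(r - h, 0); hi <- min(r + h, 1)
    (f(hi) - f(lo)) / (hi - lo) < 0
  }, logical(1))
  data.frame(phi = roots, stable = stable)
}

# named roots helper: phi_minus / phi_u / phi_plus when bistable
named_roots <- function(eq) {
  st <- eq$phi[eq$stable]
  un <- eq$phi[!eq$stable]
  if (length(st) == 2L && length(un) >= 1L) {
    list(phi_minus = min(st), phi_u = un[un > min(st) & un < max(st)][1],
         phi_plus = max(st), bistable = TRUE)
  } else {
    list(phi_minus = NA_real_, phi_u = NA_real_, phi_plus = NA_real_,
         bistable = FALSE)
  }
}

#' Full phase portrait at one point of the (rho, sigma) plane
#'
#' Combines [find_equilibria()], the potential table and the region label
#' into one object.
#'
#' @inheritParams find_equilibria
#' @param n_grid number of points of the tabulated potential.
#' @return object of class `phase_portrait` with fields `rho`, `sigma`,
#'   `roots` (data.frame), `phi_minus`, `phi_u`, `phi_plus` (NA when not
#'   bistable), `V` (data.frame phi, V), `delta_V` = `V(phi_plus) -
#'   V(phi_minus)`, and `region`.
#' @export
phase_portrait <- function(rho, sigma, params, n_grid = 401L,
                           rate_scale = NULL) {
  eq <- find_equilibria(rho, sigma, params, rate_scale)
  nr <- named_roots(eq)
  Vtab <- effective_potential(seq(0, 1, length.out = n_grid), rho, sigma,
                              params, rate_scale)
  delta_V <- NA_real_
  if (nr$bistable) {
    Vv <- potential_at(c(nr$phi_minus, nr$phi_plus), rho, sigma, params,
                       rate_scale)
    delta_V <- Vv[2] - Vv[1]
  }
  region <- classify_from(eq, nr, delta_V, Vtab$V)
  structure(list(rho = rho, sigma = sigma, roots = eq,
                 phi_minus = nr$phi_minus, phi_u = nr$phi_u,
                 phi_plus = nr$phi_plus, V = Vtab, delta_V = delta_V,
                 region = region),
            class = "phase_portrait")
}

classify_from <- function(eq, nr, delta_V, Vvals) {
  if (!nr$bistable) {
    st <- eq$phi[eq$stable]
    if (length(st) == 0L) return("degenerate")
    # the high phase is full activation; anything else is the low branch
    return(if (max(st) > 1 - 1e-9) "monostable_high" else "monostable_low")
  }
  tol <- 1e-8 * max(abs(Vvals))
  if (abs(delta_V) < tol) "coexistence"
  else if (delta_V > 0) "bistable_low_favored"   # low well is deeper
  else "bistable_high_favored"
}

#' Classify a point of the phase diagram
#'
#' Region labels: `monostable_low` / `monostable_high` (a single stable
#' phase), `bistable_low_favored` / `bistable_high_favored` (two stable
#' phases, split by the sign of `delta_V = V(phi_plus) - V(phi_minus)`),
#' and `coexistence` when `|delta_V| < 1e-8 * max|V|`.
#'
#' @inheritParams find_equilibria
#' @return a region label (character).
#' @export
classify_region <- function(rho, sigma, params, rate_scale = NULL) {
  phase_portrait(rho, sigma, params, n_grid = 101L,
                 rate_scale = rate_scale)$region
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat(sprintf("phase portrait at rho = %.6g, sigma = %.6g: %s\n",
              x$rho, x$sigma, x$region))
  print(x$roots, row.names = FALSE)
  if (!is.na(x$delta_V))
    cat(sprintf("delta_V = V(phi+) - V(phi-) = %.6g\n", x$delta_V))
  invisible(x)
}

#' @export
plot.phase_portrait <- function(x, ...) {
  plot(x$V$phi, x$V$V, type = "l", xlab = expression(phi),
       ylab = expression(V(phi)),
       main = sprintf("rho = %.3g, sigma = %.3g (%s)", x$rho, x$sigma,
                      x$region), ...)
  pts <- x$roots
  Vr <- x$V$V[vapply(pts$phi, function(p) which.min(abs(x$V$phi - p)),
                     integer(1))]
  points(pts$phi, Vr, pch = ifelse(pts$stable, 19, 1))
  invisible(x)
}

#' Saddle-node boundaries of the bistability region
#'
#' For a fixed signal `sigma`, locates the interval of enzyme ratios
#' `(rho_lo, rho_hi)` inside which the reduced dynamics has two stable
#' phases.  The boundaries (saddle-node loci) are found by bisection on
#' the stable-root count of [find_equilibria()], to a relative tolerance
#' of 1e-8 in `rho`, starting from a logarithmic scan over
#' `rho in [1e-4, 1e4]`.
#'
#' @inheritParams find_equilibria
#' @param rho_range search interval for the log scan.
#' @param n_scan number of scan points.
#' @return list with `exists` (logical) and, when `TRUE`, `rho_lo`,
#'   `rho_hi`.
#' @export
bistability_boundaries <- function(sigma, params, rho_range = c(1e-4, 1e4),
                                   n_scan = 161L, rate_scale = NULL) {
  n_stable <- function(rho) {
    eq <- find_equilibria(rho, sigma, params, rate_scale)
    sum(eq$stable)
  }
  grid <- exp(seq(log(rho_range[1]), log(rho_range[2]), length.out = n_scan))
  ns <- vapply(grid, n_stable, numeric(1))
  idx <- which(ns == 2)
  if (length(idx) == 0L) return(list(exists = FALSE))
  bisect_edge <- function(lo, hi, inside_hi) {
    # inside_hi: TRUE if 'hi' is the bistable side
    while (hi - lo > 1e-8 * max(1, hi)) {
      m <- (lo + hi) / 2
      if ((n_stable(m) == 2) == inside_hi) hi <- m else lo <- m
    }
    (lo + hi) / 2
  }
  i1 <- min(idx); i2 <- max(idx)
  rho_lo <- if (i1 == 1L) grid[1] else bisect_edge(grid[i1 - 1L], grid[i1], TRUE)
  rho_hi <- if (i2 == n_scan) grid[n_scan] else bisect_edge(grid[i2], grid[i2 + 1L], FALSE)
  list(exists = TRUE, rho_lo = rho_lo, rho_hi = rho_hi)
}

# delta_V(rho) at fixed sigma (internal)
delta_V_at <- function(rho, sigma, params, rate_scale = NULL) {
  eq <- find_equilibria(rho, sigma, params, rate_scale)
  nr <- named_roots(eq)
  if (!nr$bistable) return(NA_real_)
  Vv <- potential_at(c(nr$phi_minus, nr$phi_plus), rho, sigma, params,
                     rate_scale)
  Vv[2] - Vv[1]
}

#' Phase-coexistence line
#'
#' For each signal level `sigma`, the coexistence enzyme ratio
#' `rho_star(sigma)` is the Maxwell-type equal-depth point where the two
#' stable phases have the same effective potential,
#' `V(phi_minus) = V(phi_plus)`.  A planar interface between the phases is
#' stationary exactly on this line, which is the attractor of the
#' reservoir-driven polarization dynamics.  `rho_star` is found by
#' bisection of `delta_V(rho)` inside the bistable interval, to a relative
#' tolerance of 1e-10.
#'
#' @param sigma_grid signal levels (each must admit a bistable interval).
#' @inheritParams find_equilibria
#' @return object of class `coexistence_line`: data.frame with columns
#'   `sigma`, `rho_lo`, `rho_star`, `rho_hi`.  Signal levels where
#'   `delta_V` does not change sign inside the bistable interval get
#'   `rho_star = NA` (flagged, not fabricated).
#' @export
coexistence_line <- function(sigma_grid, params, rate_scale = NULL) {
  rows <- lapply(sigma_grid, function(sigma) {
    bb <- bistability_boundaries(sigma, params, rate_scale = rate_scale)
    if (!bb$exists)
      return(data.frame(sigma = sigma, rho_lo = NA_real_,
                        rho_star = NA_real_, rho_hi = NA_real_))
    # probe strictly inside the saddle-node loci: right at a locus the two
    # merging roots are numerically indistinguishable, so step 1% into the
    # logarithmic width of the bistable interval
    lw <- log(bb$rho_hi) - log(bb$rho_lo)
    lo <- exp(log(bb$rho_lo) + 0.01 * lw)
    hi <- exp(log(bb$rho_hi) - 0.01 * lw)
    dlo <- delta_V_at(lo, sigma, params, rate_scale)
    dhi <- delta_V_at(hi, sigma, params, rate_scale)
    star <- NA_real_
    if (is.finite(dlo) && is.finite(dhi) && dlo * dhi < 0) {
      while (hi - lo > 1e-10 * hi) {
        m <- sqrt(lo * hi)
        dm <- delta_V_at(m, sigma, params, rate_scale)
        if (!is.finite(dm)) break
        if (dlo * dm <= 0) hi <- m else { lo <- m; dlo <- dm }
      }
      star <- sqrt(lo * hi)
    }
    data.frame(sigma = sigma, rho_lo = bb$rho_lo, rho_star = star,
               rho_hi = bb$rho_hi)
  })
  structure(do.call(rbind, rows), class = c("coexistence_line", "data.frame"))
}

#' @export
plot.coexistence_line <- function(x, ...) {
  rng <- range(c(x$rho_lo, x$rho_hi), na.rm = TRUE)
  plot(NA, xlim = range(x$sigma), ylim = rng, log = "y",
       xlab = expression(sigma), ylab = expression(rho),
       main = "bistability region and coexistence line", ...)
  polygon(c(x$sigma, rev(x$sigma)), c(x$rho_lo, rev(x$rho_hi)),
          col = "lightyellow", border = NA)
  lines(x$sigma, x$rho_lo, lty = 2)
  lines(x$sigma, x$rho_hi, lty = 2)
  lines(x$sigma, x$rho_star, col = "purple", lwd = 2)
  invisible(x)
}

#' Equilibrium patch-area fraction on the coexistence line
#'
#' In the sharp-interface (thin interface) approximation the polarized
#' equilibrium consists of a cap of the activated-rich phase
#' (`phi = phi_plus`) covering an area fraction `alpha` of the membrane,
#' with the rest at `phi_minus`.  The fraction is fixed by requiring the
#' reservoir-coupled enzyme ratio of that two-phase configuration to sit
#' exactly on the coexistence line: free-enzyme concentrations follow from
#' the conservation laws evaluated on the partitioned membrane, and
#' `alpha` solves `rho(alpha) = rho_star(sigma)` (the left side is
#' strictly decreasing in `alpha`, so a bracketed root-solve applies).
#'
#' @param params a [polarity_params()] object.
#' @param sigma renormalized signal (uniform receptor activation).
#' @return list with `fraction` (area fraction of the activated-rich
#'   phase), `A_cyt`, `B_cyt`, `rho_star`, `phi_minus`, `phi_plus`,
#'   `sigma`, and `possible` (FALSE when no fraction in (0,1) can reach
#'   the coexistence line for these totals; the other entries are then NA).
#' @export
patch_area_ratio <- function(params, sigma) {
  cl <- coexistence_line(sigma, params)
  if (!is.finite(cl$rho_star))
    return(list(possible = FALSE, fraction = NA_real_, A_cyt = NA_real_,
                B_cyt = NA_real_, rho_star = NA_real_,
                phi_minus = NA_real_, phi_plus = NA_real_, sigma = sigma))
  rho_star <- cl$rho_star
  eq <- find_equilibria(rho_star, sigma, params)
  nr <- named_roots(eq)
  rho_R <- if (sigma > 0) receptor_from_sigma(sigma, params) else 0
  S <- params$S_area; V <- params$V_cyt
  phim <- nr$phi_minus; phip <- nr$phi_plus
  rho_of <- function(alpha) {
    mean_phi <- alpha * phip + (1 - alpha) * phim
    A_cyt <- params$A_tot /
      (1 + (ktil_R(params) * rho_R * S +
              ktil_X(params) * params$X_tot * S * mean_phi) / V)
    B_cyt <- params$B_tot /
      (1 + ktil_B(params) * params$X_tot * S * (1 - mean_phi) / V)
    rc <- reduced_coordinates(A_cyt, B_cyt, rho_R, params)
    list(rho = rc$rho, A_cyt = A_cyt, B_cyt = B_cyt)
  }
  g <- function(alpha) rho_of(alpha)$rho - rho_star
  lo <- 1e-9; hi <- 1 - 1e-9
  if (g(lo) < 0 || g(hi) > 0)
    return(list(possible = FALSE, fraction = NA_real_, A_cyt = NA_real_,
                B_cyt = NA_real_, rho_star = rho_star, phi_minus = phim,
                phi_plus = phip, sigma = sigma))
  alpha <- uniroot(g, c(lo, hi), tol = 1e-12)$root
  res <- rho_of(alpha)
  list(possible = TRUE, fraction = alpha, A_cyt = res$A_cyt,
       B_cyt = res$B_cyt, rho_star = rho_star, phi_minus = phim,
       phi_plus = phip, sigma = sigma)
}

#' Tabulate the phase diagram over a (sigma, rho) grid
#'
#' @param rho_grid,sigma_grid grids of reduced coordinates.
#' @param params a [polarity_params()] object.
#' @return data.frame with one row per (sigma, rho): `sigma`, `rho`,
#'   `region`, `phi_minus`, `phi_u`, `phi_plus`, `delta_V`, suitable for
#'   delimited-table export via [utils::write.csv()].
#' @export
region_map <- function(rho_grid, sigma_grid, params) {
  rows <- lapply(sigma_grid, function(sg) {
    do.call(rbind, lapply(rho_grid, function(rh) {
      pp <- phase_portrait(rh, sg, params, n_grid = 101L)
      data.frame(sigma = sg, rho = rh, region = pp$region,
                 phi_minus = pp$phi_minus, phi_u = pp$phi_u,
                 phi_plus = pp$phi_plus, delta_V = pp$delta_V)
    }))
  })
  do.call(rbind, rows)
}

#' @describeIn region_map plot a region map as an image in the
#'   (sigma, log10 rho) plane.
#' @param map a data.frame from `region_map()`.
#' @param ... passed to [graphics::image()].
#' @export
plot_region_map <- function(map, ...) {
  levels <- c("monostable_low", "bistable_low_favored", "coexistence",
              "bistable_high_favored", "monostable_high")
  sig <- sort(unique(map$sigma)); rho <- sort(unique(map$rho))
  z <- matrix(match(map$region, levels),
              nrow = length(sig), ncol = length(rho), byrow = FALSE)
  image(sig, log10(rho), z, col = hcl.colors(5, "Temps"),
        xlab = expression(sigma), ylab = expression(log[10](rho)), ...)
  invisible(map)
}
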
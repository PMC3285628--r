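#' Model parameters for the bistable polarity pathway
#'
#' Bundles every rate constant, Michaelis constant, molecule total and
#' geometric quantity of the membrane polarity model, and validates them.
#' Internal units are molecules, micrometres and seconds: surface densities
#' in molecules/um^2, cytosolic concentrations in molecules/um^3 (1 nM =
#' 0.6022 molecules/um^3, see [nM_to_per_um3()]), bimolecular recruitment
#' rates in um^3/s, first-order rates in 1/s.
#'
#' The two signaling species `X*` (activated) and `X0` (unactivated) live
#' on the membrane with a conserved pointwise total `X_tot`.  The enzyme
#' `A` converts `X0 -> X*` and is recruited to the membrane by activated
#' receptors (rate `k_on_R`, bound species `a_R`) and by `X*` itself
#' (rate `k_on_X`, bound species `a_X`, the reinforcing feedback loop).
#' The enzyme `B` converts `X* -> X0` and is recruited by `X0` (rate
#' `k_on_B`, bound species `b`).  Free enzymes form a shared well-mixed
#' cytosolic reservoir of `A_tot`/`B_tot` total copies.
#'
#' @param k_cat_A,k_cat_B catalytic rates of the activating/deactivating
#'   enzyme (1/s).
#' @param K_A,K_B Michaelis constants of the two conversion arms
#'   (molecules/um^2).
#' @param k_on_R recruitment rate of cytosolic A per unit activated-receptor
#'   density (um^3/s).
#' @param k_on_X recruitment rate of cytosolic A per unit `X*` density
#'   (um^3/s), the A <- X* feedback loop.
#' @param k_on_B recruitment rate of cytosolic B per unit `X0` density
#'   (um^3/s), the B <- X0 feedback loop.
#' @param k_off_AR,k_off_AX,k_off_B membrane dissociation rates of the three
#'   bound-enzyme species (1/s).
#' @param A_tot,B_tot total enzyme copy numbers (dimensionless counts).
#' @param X_tot total surface density of the signaling molecule,
#'   `x* + x0` at every point (molecules/um^2).
#' @param D lateral diffusivity of `X*` and `X0` on the membrane (um^2/s).
#'   Bound enzymes do not diffuse laterally.
#' @param R radius of the spherical membrane (um).  `S_area` and `V_cyt`
#'   default to the sphere surface `4*pi*R^2` and volume `4/3*pi*R^3`.
#' @param S_area total membrane area (um^2); overrides the spherical default.
#' @param V_cyt cytosolic volume (um^3); overrides the spherical default.
#' @param signal a signal schedule created by [signal_schedule()] mapping
#'   (position, time) to the activated-receptor density `rho_R`.
#'
#' @return An object of class `polarity_params`: a validated list with the
#'   above fields plus the derived surface-to-volume conversion factor
#'   `chi = S_area / V_cyt` (1/um), which converts a uniform surface
#'   density into the volume concentration obtained by releasing it into
#'   the cytosol.
#'
#' @examples
#' p <- polarity_params()
#' p$chi * p$V_cyt / p$S_area  # == 1, the round-trip identity
#' @seealso [signal_schedule()], [reduced_coordinates()], [find_equilibria()]
#' @export
polarity_params <- function(k_cat_A = 0.05, k_cat_B = 0.05,
                            K_A = 60, K_B = 60,
                            k_on_R = 0.012, k_on_X = 0.012, k_on_B = 0.012,
                            k_off_AR = 1, k_off_AX = 1, k_off_B = 1,
                            A_tot = 60000, B_tot = 120000,
                            X_tot = 600,
                            D = 0.1,
                            R = 5,
                            S_area = NULL, V_cyt = NULL,
                            signal = signal_schedule("constant", rho_R = 0)) {
  if (is.null(S_area)) S_area <- 4 * pi * R^2
  if (is.null(V_cyt)) V_cyt <- 4 / 3 * pi * R^3
  p <- structure(list(
    k_cat_A = k_cat_A, k_cat_B = k_cat_B,
    K_A = K_A, K_B = K_B,
    k_on_R = k_on_R, k_on_X = k_on_X, k_on_B = k_on_B,
    k_off_AR = k_off_AR, k_off_AX = k_off_AX, k_off_B = k_off_B,
    A_tot = A_tot, B_tot = B_tot,
    X_tot = X_tot, D = D,
    R = R, S_area = S_area, V_cyt = V_cyt,
    chi = S_area / V_cyt,
    signal = signal
  ), class = "polarity_params")
  validate_params(p)
}

#' Validate a `polarity_params` object
#'
#' Checks sign constraints (all rates and totals nonnegative, Michaelis
#' constants, totals, geometry strictly positive), the consistency of the
#' derived radius with `S_area`, and the round-trip identity of the
#' surface-to-volume factor `chi`.
#'
#' @param p a `polarity_params` object.
#' @return `p`, invisibly unchanged, or an error.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "polarity_params"))
  nonneg <- c("k_cat_A", "k_cat_B", "k_on_R", "k_on_X", "k_on_B",
              "k_off_AR", "k_off_AX", "k_off_B", "A_tot", "B_tot", "D")
  pos <- c("K_A", "K_B", "X_tot", "S_area", "V_cyt", "chi")
  for (nm in nonneg) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", nm, "' must be a single nonnegative number")
  }
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive number")
  }
  # chi round trip: a uniform surface density d spread over S_area and
  # released into V_cyt gives concentration d * S / V = d * chi
  d <- 1.0
  if (abs(d * p$S_area / p$V_cyt - d * p$chi) > 1e-12 * p$chi)
    stop("chi is inconsistent with S_area / V_cyt")
  if (!inherits(p$signal, "signal_schedule"))
    stop("'signal' must be a signal_schedule object")
  invisible(p)
}

#' @export
print.polarity_params <- function(x, ...) {
  cat("Membrane polarity model parameters\n")
  cat(sprintf("  catalysis : k_cat_A = %g, k_cat_B = %g 1/s; K_A = %g, K_B = %g /um^2 (kappa = %.3g, %.3g)\n",
              x$k_cat_A, x$k_cat_B, x$K_A, x$K_B, x$K_A / x$X_tot, x$K_B / x$X_tot))
  cat(sprintf("  shuttling : k_on R/X/B = %g/%g/%g um^3/s, k_off = %g/%g/%g 1/s\n",
              x$k_on_R, x$k_on_X, x$k_on_B, x$k_off_AR, x$k_off_AX, x$k_off_B))
  cat(sprintf("  totals    : A_tot = %g, B_tot = %g copies; X_tot = %g /um^2\n",
              x$A_tot, x$B_tot, x$X_tot))
  cat(sprintf("  geometry  : R = %g um, S = %.4g um^2, V = %.4g um^3, chi = %.4g /um; D = %g um^2/s\n",
              x$R, x$S_area, x$V_cyt, x$chi, x$D))
  cat(sprintf("  signal    : %s\n", format(x$signal)))
  invisible(x)
}

# binding affinities k_on / k_off (um^3); used throughout the reductions
ktil_R <- function(p) if (p$k_off_AR > 0) p$k_on_R / p$k_off_AR else 0
ktil_X <- function(p) if (p$k_off_AX > 0) p$k_on_X / p$k_off_AX else 0
ktil_B <- function(p) if (p$k_off_B > 0) p$k_on_B / p$k_off_B else 0

kappa_A <- function(p) p$K_A / p$X_tot
kappa_B <- function(p) p$K_B / p$X_tot

#' Convert between nM and molecules per cubic micrometre
#'
#' 1 nM = 1e-9 mol/L * N_Avogadro = 0.6022 molecules/um^3.
#'
#' @param x concentration value(s).
#' @return the converted value(s).
#' @export
nM_to_per_um3 <- function(x) x * 0.60221408

#' @rdname nM_to_per_um3
#' @export
per_um3_to_nM <- function(x) x / 0.60221408
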
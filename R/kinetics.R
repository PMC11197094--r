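#' Marcus activation free energy for electron transfer
#'
#' Evaluates the classical Marcus expression
#' \deqn{\Delta G^\ddagger = \frac{\lambda}{4}\left(1 + \frac{\Delta G}{\lambda}\right)^2}
#' for an outer-sphere single-electron-transfer step. The barrier is a
#' parabola in the reaction free energy with its apex (zero barrier) at
#' \eqn{\Delta G = -\lambda}; reactions more exergonic than that fall in the
#' inverted region and slow down again. The bare parabola is used throughout,
#' with no quantum correction in the inverted region.
#'
#' @param delta_g Reaction free energy, kcal mol^-1. Vectorized.
#' @param lamda Reorganization energy, kcal mol^-1, strictly positive.
#'   Recycled against `delta_g`.
#' @return Activation free energy, kcal mol^-1 (always >= 0).
#' @examples
#' marcus_barrier(19.0, 9.3)    # 21.5
#' marcus_barrier(-16.8, 12.7)  # 0.33, inverted region
#' @export
marcus_barrier <- function(delta_g, lamda) {
  if (!is.numeric(delta_g) || !is.numeric(lamda))
    stop("delta_g and lamda must be numeric")
  if (any(!is.finite(lamda)) || any(lamda <= 0))
    stop("reorganization energy lamda must be finite and > 0")
  (lamda / 4) * (1 + delta_g / lamda)^2
}

#' Marcus parabola: barrier as a function of reaction free energy
#'
#' Pointwise [marcus_barrier()] over a grid of reaction free energies for a
#' fixed reorganization energy, the standard graphical summary of how
#' electron-transfer barriers respond to driving force. The apex (maximum
#' rate, zero barrier) sits at `delta_g = -lamda`.
#'
#' @param lamda Reorganization energy, kcal mol^-1, > 0.
#' @param dg_grid Numeric grid of reaction free energies, kcal mol^-1.
#' @return A data.frame with columns `delta_g` and `delta_g_act`.
#' @export
marcus_parabola <- function(lamda, dg_grid) {
  stopifnot(length(lamda) == 1L)
  data.frame(delta_g = dg_grid,
             delta_g_act = marcus_barrier(dg_grid, lamda))
}

#' Eyring transition-state-theory rate constant
#'
#' Conventional TST with optional reaction-path degeneracy and tunneling
#' correction:
#' \deqn{k = \sigma\,\kappa\,\frac{k_B T}{h}\, e^{-\Delta G^\ddagger / RT}}
#' referenced to the 1 mol/L standard state, so a bimolecular activation free
#' energy in kcal mol^-1 yields k in M^-1 s^-1.
#'
#' @param dg_act Activation free energy, kcal mol^-1. Vectorized.
#' @param ctx A [kinetic_context()] (or a temperature in K). Default 298.15 K.
#' @param sigma Reaction-path degeneracy, integer >= 1. Default 1.
#' @param kappa Tunneling correction factor >= 1. Default 1 (no tunneling).
#'   Hydrogen-transfer channels computed with a full tunneling treatment need
#'   an explicit `kappa`; see the package vignette.
#' @return Rate constant(s), M^-1 s^-1 for bimolecular steps.
#' @examples
#' eyring_rate(0)      # ~6.21e12, the bare prefactor
#' eyring_rate(19.1)   # ~6.2e-2
#' @export
eyring_rate <- function(dg_act, ctx = kinetic_context(), sigma = 1, kappa = 1) {
  ctx <- .as_ctx(ctx)
  if (any(!is.finite(dg_act))) stop("dg_act must be finite")
  if (any(sigma < 1) || any(sigma != round(sigma)))
    stop("sigma must be an integer >= 1")
  if (any(!is.finite(kappa)) || any(kappa < 1))
    stop("kappa must be >= 1")
  sigma * kappa * ctx$prefactor * exp(-dg_act / ctx$rt)
}

#' Invert an Eyring rate constant back to its activation free energy
#'
#' Companion to [eyring_rate()]: recovers `dg_act = RT * log(prefactor / k)`
#' (for sigma = kappa = 1). Used for round-trip checks and for reading
#' effective barriers off tabulated rate constants.
#'
#' @inheritParams eyring_rate
#' @param k Rate constant(s), M^-1 s^-1, > 0.
#' @return Activation free energy, kcal mol^-1.
#' @export
eyring_barrier <- function(k, ctx = kinetic_context()) {
  ctx <- .as_ctx(ctx)
  if (any(k <= 0)) stop("k must be > 0")
  ctx$rt * log(ctx$prefactor / k)
}

#' Stokes-Einstein diffusion coefficient
#'
#' \eqn{D = k_B T / (6 \pi \eta a)} for a sphere of hydrodynamic radius `a`
#' in a solvent of viscosity `eta`.
#'
#' @param radius Hydrodynamic radius in Angstrom, > 0.
#' @param viscosity Dynamic viscosity in Pa s, > 0.
#' @param temperature Temperature in K, > 0. Default 298.15.
#' @return Diffusion coefficient in m^2 s^-1.
#' @examples
#' stokes_einstein_diffusion(2, 8.91e-4)  # ~1.23e-9 m^2/s in water
#' @export
stokes_einstein_diffusion <- function(radius, viscosity, temperature = 298.15) {
  if (any(radius <= 0) || any(viscosity <= 0) || any(temperature <= 0))
    stop("radius, viscosity and temperature must all be > 0")
  .kB * temperature / (6 * pi * viscosity * radius * 1e-10)
}

#' Solvent and reactant-size parameters for the diffusion limit
#'
#' The encounter-rate calculation needs hydrodynamic radii for both partners
#' and the solvent viscosity. None of these are refined quantities here; the
#' defaults (4 Angstrom for a flavonoid or its Cu complex, 2 Angstrom for a
#' small radical, water viscosity 8.91e-4 Pa s at 298.15 K) give diffusion
#' limits of the right order (~1e10 M^-1 s^-1) and are all overridable.
#'
#' @param radius_a,radius_b Hydrodynamic radii in Angstrom, > 0.
#' @param viscosity Dynamic viscosity in Pa s, > 0.
#' @param temperature Temperature in K. Default 298.15.
#' @return An object of class `diffusion_spec`.
#' @export
diffusion_spec <- function(radius_a = 4.0, radius_b = 2.0,
                           viscosity = 8.91e-4, temperature = 298.15) {
  if (any(c(radius_a, radius_b, viscosity, temperature) <= 0))
    stop("all diffusion parameters must be > 0")
  structure(list(radius_a = radius_a, radius_b = radius_b,
                 viscosity = viscosity, temperature = temperature),
            class = "diffusion_spec")
}

#' Smoluchowski diffusion-limited rate constant
#'
#' Encounter-controlled bimolecular rate
#' \eqn{k_D = 4 \pi (r_A + r_B)(D_A + D_B) N_A}, with Stokes-Einstein
#' diffusion coefficients, converted to M^-1 s^-1. This is the ceiling any
#' activated rate is capped by in solution.
#'
#' @param d A [diffusion_spec()].
#' @return Diffusion-limited rate constant, M^-1 s^-1.
#' @examples
#' smoluchowski_rate(diffusion_spec(2, 2))  # ~7.4e9 in water
#' @export
smoluchowski_rate <- function(d = diffusion_spec()) {
  stopifnot(inherits(d, "diffusion_spec"))
  da <- stokes_einstein_diffusion(d$radius_a, d$viscosity, d$temperature)
  db <- stokes_einstein_diffusion(d$radius_b, d$viscosity, d$temperature)
  r_sum <- (d$radius_a + d$radius_b) * 1e-10          # m
  k_m3 <- 4 * pi * r_sum * (da + db) * .NA            # m^3 mol^-1 s^-1
  k_m3 * 1e3                                          # L mol^-1 s^-1
}

#' Collins-Kimball apparent rate constant
#'
#' Combines an activated (TST) rate with the diffusion limit:
#' \eqn{k_{app} = k_{act} k_D / (k_{act} + k_D)}. The apparent rate never
#' exceeds either input; it reduces to the activated rate for slow reactions
#' and plateaus at the diffusion limit for fast ones.
#'
#' @param k_act Activated rate constant(s), >= 0, M^-1 s^-1.
#' @param k_d Diffusion-limited rate constant(s), >= 0, M^-1 s^-1.
#' @return Apparent rate constant(s), M^-1 s^-1. Returns 0 where both
#'   arguments are 0.
#' @export
collins_kimball <- function(k_act, k_d) {
  if (any(k_act < 0) || any(k_d < 0)) stop("rate constants must be >= 0")
  out <- numeric(length(k_act <- rep_len(k_act, max(length(k_act), length(k_d)))))
  k_d <- rep_len(k_d, length(k_act))
  both_zero <- k_act == 0 & k_d == 0
  out[!both_zero] <- k_act[!both_zero] * k_d[!both_zero] /
    (k_act[!both_zero] + k_d[!both_zero])
  out
}

#' Recover a reorganization energy from (delta G, delta G-double-dagger) pairs
#'
#' Least-squares fit of the Marcus parabola to observed activation free
#' energies: minimizes the residual sum of squares of
#' `dg_act - (lamda/4)(1 + dg/lamda)^2` over `lamda > 0` via [stats::nls()].
#' With noise-free data generated from the parabola the fit recovers the
#' generating reorganization energy exactly; with noisy data the returned
#' standard error quantifies the recovery uncertainty.
#'
#' @param delta_g Reaction free energies, kcal mol^-1.
#' @param dg_act Observed activation free energies, kcal mol^-1.
#' @param start Starting value for the reorganization energy. Defaults to a
#'   moment-based guess (4 * mean barrier at delta_g ~ 0, falling back to
#'   the overall mean barrier scale).
#' @return A list with `lamda` (estimate), `se` (standard error), and the
#'   underlying `nls` fit.
#' @export
fit_reorganization_energy <- function(delta_g, dg_act, start = NULL) {
  stopifnot(length(delta_g) == length(dg_act), length(delta_g) >= 3L)
  if (is.null(start)) {
    near0 <- abs(delta_g) < stats::quantile(abs(delta_g), 0.25)
    start <- 4 * mean(dg_act[near0])
    if (!is.finite(start) || start <= 0) start <- max(4 * mean(dg_act), 1)
  }
  df <- data.frame(dg = delta_g, dga = dg_act)
  fit <- stats::nls(dga ~ (lamda / 4) * (1 + dg / lamda)^2, data = df,
                    start = list(lamda = start),
                    lower = 1e-6, algorithm = "port")
  sm <- summary(fit)
  list(lamda = unname(stats::coef(fit)["lamda"]),
       se = sm$coefficients["lamda", "Std. Error"],
       fit = fit)
}
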
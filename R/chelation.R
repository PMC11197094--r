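#' Equilibrium constant from a reaction free energy
#'
#' \eqn{K = e^{-\Delta G / RT}}. Used for the metal-complexation equilibria;
#' strictly decreasing in the free energy and multiplicative over composed
#' reactions.
#'
#' @param delta_g Reaction free energy, kcal mol^-1. Vectorized.
#' @param ctx A [kinetic_context()].
#' @return Dimensionless equilibrium constant(s).
#' @export
equilibrium_constant <- function(delta_g, ctx = kinetic_context()) {
  ctx <- .as_ctx(ctx)
  exp(-delta_g / ctx$rt)
}

#' Apparent chelation constant over parallel pathways
#'
#' Combines the equilibrium constants of the individual chelation routes
#' (motif x stoichiometry) into one apparent constant. The default is the
#' parallel-equilibria convention, the plain sum of the pathway constants;
#' `method = "product"` instead multiplies them, the convention appropriate
#' when the constants describe successive steps of a bis-complex. Which
#' convention matches a given tabulation is a modelling choice; see the
#' vignette.
#'
#' @param k_list Numeric vector of pathway equilibrium constants (>= 1 value).
#' @param method `"sum"` (default, parallel pathways) or `"product"`
#'   (stepwise constants).
#' @return The apparent equilibrium constant.
#' @export
apparent_constant <- function(k_list, method = c("sum", "product")) {
  method <- match.arg(method)
  if (!length(k_list)) stop("need at least one pathway constant")
  if (any(k_list < 0)) stop("equilibrium constants must be >= 0")
  if (method == "sum") sum(k_list) else prod(k_list)
}

#' Boltzmann populations of competing pathways
#'
#' Maxwell-Boltzmann weights over pathway free energies:
#' \eqn{f_i = e^{-\Delta G_i/RT} / \sum_j e^{-\Delta G_j/RT}}. Evaluated
#' relative to the minimum energy so arbitrarily shifted inputs neither
#' overflow nor change the result.
#'
#' @param delta_g_list Numeric vector of free energies, kcal mol^-1.
#' @param ctx A [kinetic_context()].
#' @return Fractions summing to 1, in input order.
#' @examples
#' boltzmann_fractions(c(0, 1.03))  # ~0.85 / 0.15
#' @export
boltzmann_fractions <- function(delta_g_list, ctx = kinetic_context()) {
  ctx <- .as_ctx(ctx)
  if (!length(delta_g_list)) stop("need at least one value")
  w <- exp(-(delta_g_list - min(delta_g_list)) / ctx$rt)
  w / sum(w)
}

#' Marcus-activated reduction kinetics of a metal center
#'
#' Rate constant for the reduction of a (complexed or free) metal ion by a
#' reductant whose barrier follows Marcus theory: the reorganization energy
#' and reaction free energy give the barrier, Eyring gives the activated
#' rate, Collins-Kimball caps it at the diffusion limit, and the result is
#' scaled by the pH-dependent molar fractions of both partners.
#'
#' @param delta_g Reaction free energy, kcal mol^-1.
#' @param lamda Reorganization energy, kcal mol^-1, > 0.
#' @param ctx A [kinetic_context()].
#' @param diffusion A [diffusion_spec()].
#' @param reductant_fraction Molar fraction of the reactive reductant form at
#'   the working pH (default 1).
#' @param species_fraction Molar fraction of the metal-bearing species
#'   (default 1).
#' @return A list with `delta_g_act`, `k_tst`, `k_d`, `k_app` and the
#'   fraction-scaled `k`.
#' @export
reduction_kinetics <- function(delta_g, lamda, ctx = kinetic_context(),
                               diffusion = diffusion_spec(),
                               reductant_fraction = 1, species_fraction = 1) {
  stopifnot(reductant_fraction >= 0, reductant_fraction <= 1,
            species_fraction >= 0, species_fraction <= 1)
  dga <- marcus_barrier(delta_g, lamda)
  k_tst <- eyring_rate(dga, ctx)
  k_d <- smoluchowski_rate(diffusion)
  k_app <- collins_kimball(k_tst, k_d)
  list(delta_g_act = dga, k_tst = k_tst, k_d = k_d, k_app = k_app,
       k = k_app * reductant_fraction * species_fraction)
}

#' Classify complexes as metal-sequestering (OIL-1) antioxidant agents
#'
#' Compares the reduction rate of each ligand-bound metal center against the
#' free-ion reference for the same reductant. A complex that is reduced more
#' slowly protects the metal from re-entering the radical-generating redox
#' cycle; one reduced faster is pro-oxidant for that reductant. A complex
#' slower than the reference with *every* reductant tested is flagged as an
#' OIL-1 agent. Ties are classified `"down"` (conservative in favor of the
#' ligand).
#'
#' @param comparisons A data.frame with columns `complex_label`, `reductant`,
#'   `k_complex` and `k_reference` (all rates > 0 for references).
#' @return The input extended with `direction` (`"up"`/`"down"`) and
#'   `fold_change` (>= 1), plus an `oil1_agent` logical column (per complex:
#'   down with every reductant).
#' @export
oil1_classify <- function(comparisons) {
  df <- as.data.frame(comparisons)
  needed <- c("complex_label", "reductant", "k_complex", "k_reference")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$k_reference <= 0)) stop("reference rates must be > 0")
  df$direction <- ifelse(df$k_complex > df$k_reference, "up", "down")
  df$fold_change <- pmax(df$k_complex / df$k_reference,
                         df$k_reference / df$k_complex)
  down_all <- tapply(df$direction == "down", df$complex_label, all)
  df$oil1_agent <- unname(down_all[df$complex_label])
  df
}

#' SET scavenging rates of metal complexes toward the hydroxyl radical
#'
#' OIL-2 activity: once a hydroxyl radical is generated at the metal center,
#' the surrounding ligand can intercept it. Electron-transfer channels are
#' evaluated exactly like [reduction_kinetics()] but with no reductant
#' speciation (the hydroxyl radical has no acid-base equilibrium in the
#' working range).
#'
#' @param records A data.frame with columns `complex_label`, `motif` and the
#'   Marcus inputs `delta_g`, `lamda` (kcal/mol).
#' @param ctx A [kinetic_context()].
#' @param diffusion A [diffusion_spec()].
#' @return The input extended with `delta_g_act`, `k_tst`, `k_d`, `k_app`.
#' @export
oil2_set_rates <- function(records, ctx = kinetic_context(),
                           diffusion = diffusion_spec()) {
  df <- as.data.frame(records)
  stopifnot(all(c("delta_g", "lamda") %in% names(df)))
  df$delta_g_act <- marcus_barrier(df$delta_g, df$lamda)
  df$k_tst <- eyring_rate(df$delta_g_act, ctx)
  df$k_d <- smoluchowski_rate(diffusion)
  df$k_app <- collins_kimball(df$k_tst, df$k_d)
  df
}

#' Thermochemical screen of hydrogen-transfer and adduct pathways on complexes
#'
#' For the non-SET OIL-2 channels no explicit rate constants are meaningful:
#' hydroxyl-radical reactions that are thermodynamically allowed run at or
#' beyond the diffusion limit (Bell-Evans-Polanyi reasoning), so the screen
#' partitions the sites by the sign of the reaction free energy and ranks
#' them by exergonicity instead of emitting rates.
#'
#' @param delta_g_map A data.frame with columns `site`, `mechanism` and
#'   `delta_g`; any extra identifying columns are preserved.
#' @return The input with `classification` (`"exergonic"`/`"endergonic"`) and
#'   `rank` (1 = most exergonic within each mechanism), sorted by mechanism
#'   then rank.
#' @export
oil2_thermo_screen <- function(delta_g_map) {
  df <- as.data.frame(delta_g_map)
  stopifnot(all(c("site", "mechanism", "delta_g") %in% names(df)))
  df$classification <- ifelse(df$delta_g < 0, "exergonic", "endergonic")
  df$rank <- stats::ave(df$delta_g, df$mechanism,
                        FUN = function(g) rank(g, ties.method = "first"))
  df[order(df$mechanism, df$rank), , drop = FALSE]
}
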
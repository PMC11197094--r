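#' Thermochemical feasibility of biomolecule repair
#'
#' Screens the hydrogen- or electron-donating channels through which an
#' antioxidant can restore an oxidized biomolecule model (a damaged lipid,
#' amino-acid residue or nucleoside). Channels with a reaction free energy at
#' or above the threshold are discarded; a target retaining no channel is
#' declared not repairable by this antioxidant.
#'
#' @param target A data.frame of donor pathways for one repair target, with
#'   columns `site` and `delta_g` (kcal/mol); extra columns preserved.
#' @param threshold Endergonicity cutoff, kcal mol^-1. Default 10, matching
#'   the screening used for direct scavenging.
#' @return A list with `retained` (the surviving rows), `excluded`, and
#'   `repairable` (logical).
#' @export
repair_feasibility <- function(target, threshold = 10.0) {
  df <- as.data.frame(target)
  if (!nrow(df))
    return(list(retained = df, excluded = df, repairable = FALSE))
  stopifnot("delta_g" %in% names(df), is.finite(threshold))
  keep <- df$delta_g < threshold
  list(retained = df[keep, , drop = FALSE],
       excluded = df[!keep, , drop = FALSE],
       repairable = any(keep))
}

#' Species-resolved overall repair rate constants
#'
#' Weights each antioxidant species' total repair rate by its own molar
#' fraction at the working pH: `k_overall_j = f_j(pH) * k_total_j`. Unlike
#' direct radical scavenging there is no radical acid-base factor - the
#' partner is the damaged biomolecule itself.
#'
#' @param k_totals Per-species total rate constants, one per ladder state
#'   (ladder order). `NA` entries (species with no retained pathway)
#'   propagate as `NA`.
#' @param ladder A [protonation_ladder()].
#' @param ph Working pH. Default 7.4.
#' @return A list with `k_overall` (named per species) and `fractions`.
#' @export
repair_overall <- function(k_totals, ladder, ph = 7.4) {
  stopifnot(inherits(ladder, "protonation_ladder"))
  if (length(k_totals) != length(ladder$labels))
    stop("need one k_total per ladder state (got ", length(k_totals),
         " for ", length(ladder$labels), " states)")
  f <- molar_fractions(ladder, ph)
  list(k_overall = stats::setNames(as.numeric(k_totals) * f, ladder$labels),
       fractions = f)
}

#' Feasibility of antioxidant regeneration by superoxide
#'
#' After donating a hydrogen atom or an electron the spent antioxidant
#' radical can be restored by reduction (by the abundant superoxide anion)
#' followed by protonation from the solvent. This assessment flags each
#' reduction step as exergonic or endergonic, marks steps fast enough to run
#' at an appreciable fraction of the diffusion limit, and verifies that the
#' closing protonation is favorable. A cycle is `feasible` when every
#' reduction step is exergonic and every available protonation free energy is
#' negative.
#'
#' @param steps A data.frame with columns `species`, `site_or_set`, `delta_g`
#'   and `delta_g_act` (kcal/mol), and optionally `delta_g_protonation`
#'   (kcal/mol, `NA` for electron-transfer steps that need no protonation).
#' @param ctx A [kinetic_context()].
#' @param diffusion A [diffusion_spec()] for the diffusion-limit comparison.
#' @param diffusion_ratio Fraction of the diffusion limit above which a step
#'   is labeled diffusion-limited. Default 0.5.
#' @return A list with `steps` (input plus `exergonic`, `k_app`,
#'   `diffusion_limited`, `protonation_favorable`), and overall flags
#'   `feasible` and `broken_at` (row indices of endergonic steps).
#' @export
regeneration_assess <- function(steps, ctx = kinetic_context(),
                                diffusion = diffusion_spec(),
                                diffusion_ratio = 0.5) {
  df <- as.data.frame(steps)
  stopifnot(all(c("delta_g", "delta_g_act") %in% names(df)))
  if (is.null(df$delta_g_protonation)) df$delta_g_protonation <- NA_real_
  df$exergonic <- df$delta_g < 0
  k_d <- smoluchowski_rate(diffusion)
  df$k_app <- collins_kimball(eyring_rate(df$delta_g_act, ctx), k_d)
  df$diffusion_limited <- df$k_app >= diffusion_ratio * k_d
  df$protonation_favorable <- ifelse(is.na(df$delta_g_protonation), NA,
                                     df$delta_g_protonation < 0)
  broken <- which(!df$exergonic)
  list(steps = df,
       feasible = !length(broken) &&
         all(df$protonation_favorable[!is.na(df$protonation_favorable)]),
       broken_at = broken)
}

#' Site-reactivity orderings for hydrogen-donating sites
#'
#' Emits both orderings of donor sites: by reaction free energy
#' (thermodynamic) and by activation free energy (kinetic). The two need not
#' agree - a more exergonic site can sit behind a higher barrier - so relying
#' on the thermodynamic ordering alone misranks reactivity; both are
#' returned, labeled.
#'
#' @param pathways A data.frame with columns `site`, `delta_g`, `delta_g_act`.
#' @return A list with character vectors `by_delta_g` and `by_barrier`
#'   (most reactive first).
#' @export
site_reactivity_order <- function(pathways) {
  df <- as.data.frame(pathways)
  stopifnot(all(c("site", "delta_g", "delta_g_act") %in% names(df)))
  list(by_delta_g = df$site[order(df$delta_g)],
       by_barrier = df$site[order(df$delta_g_act)])
}
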
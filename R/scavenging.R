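#' Construct and validate a table of elementary reaction pathways
#'
#' The atom of every computation in the package is one elementary reaction
#' channel: an antioxidant species reacting with the radical through one
#' mechanism at one site in one medium, together with its energetics. This
#' helper normalizes a data.frame to the pathway schema, fills the optional
#' columns, and runs the structural checks.
#'
#' Required columns: `species`, `mechanism` (one of `"SET"`, `"fHAT"`,
#' `"RAF"`), `site`, `medium`. Energetic columns: `delta_g` (kcal/mol),
#' `delta_g_act` (kcal/mol, may be NA), `lamda` (kcal/mol, required for SET
#' rows lacking `delta_g_act`), `kappa` (tunneling, >= 1, default 1), `sigma`
#' (degeneracy, >= 1, default 1). Unknown columns are preserved.
#'
#' @param df A data.frame holding pathway rows.
#' @return The validated data.frame with class `pathway_table` prepended.
#' @export
pathway_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("species", "mechanism", "site", "medium")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("pathway table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("delta_g", "delta_g_act", "lamda", "kappa", "sigma"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  df$kappa[is.na(df$kappa)] <- 1
  df$sigma[is.na(df$sigma)] <- 1
  bad_mech <- !df$mechanism %in% c("SET", "fHAT", "RAF")
  if (any(bad_mech))
    stop("unknown mechanism(s) in row(s) ",
         paste(which(bad_mech), collapse = ", "),
         ": must be SET, fHAT or RAF")
  if (any(df$kappa < 1) || any(df$sigma < 1))
    stop("kappa and sigma must be >= 1")
  class(df) <- c("pathway_table", class(df))
  df
}

#' Thermochemical screening of reaction pathways
#'
#' Retains the channels worth a kinetic evaluation: all exergonic pathways,
#' endergonic hydrogen-transfer and adduct-formation pathways with a reaction
#' free energy below the threshold (such channels can still matter when fast
#' follow-up chemistry provides the driving force), and *all* electron-transfer
#' pathways regardless of their reaction free energy, because SET barriers
#' follow Marcus theory rather than the driving force alone.
#'
#' @param records A [pathway_table()] (or coercible data.frame).
#' @param dg_threshold Endergonicity cutoff in kcal mol^-1 for non-SET
#'   pathways. Default 10.
#' @return The retained rows, same schema.
#' @export
screen_pathways <- function(records, dg_threshold = 10.0) {
  records <- pathway_table(records)
  stopifnot(is.finite(dg_threshold))
  keep <- records$mechanism == "SET" |
    (!is.na(records$delta_g) & records$delta_g < dg_threshold)
  records[keep, , drop = FALSE]
}

#' Per-pathway rate constants with diffusion correction
#'
#' Evaluates each pathway's activated (TST) rate, the diffusion limit of its
#' medium, and the Collins-Kimball apparent rate. SET rows without a tabulated
#' activation free energy get one from [marcus_barrier()] using their
#' reorganization energy; other rows must carry `delta_g_act`.
#'
#' @param records A [pathway_table()].
#' @param ctx A [kinetic_context()].
#' @param diffusion A [diffusion_spec()] used for every row, or a named list
#'   of specs keyed by medium (e.g. `list(water = ..., lipid = ...)`).
#' @return A data.frame extending the input with `delta_g_act_eff` (the
#'   barrier actually used), `k_tst`, `k_d` and `k_app` (all M^-1 s^-1).
#' @export
evaluate_rates <- function(records, ctx = kinetic_context(),
                           diffusion = diffusion_spec()) {
  records <- pathway_table(records)
  ctx <- .as_ctx(ctx)
  dga <- records$delta_g_act
  need <- is.na(dga)
  set_need <- need & records$mechanism == "SET"
  if (any(set_need)) {
    ok <- !is.na(records$lamda[set_need])
    if (!all(ok))
      stop("SET row(s) without delta_g_act need lamda: row(s) ",
           paste(which(set_need)[!ok], collapse = ", "))
    dga[set_need] <- marcus_barrier(records$delta_g[set_need],
                                    records$lamda[set_need])
  }
  if (anyNA(dga))
    stop("row(s) lacking a usable activation free energy: ",
         paste(which(is.na(dga)), collapse = ", "))
  k_d <- if (inherits(diffusion, "diffusion_spec")) {
    rep(smoluchowski_rate(diffusion), nrow(records))
  } else {
    unknown <- setdiff(unique(records$medium), names(diffusion))
    if (length(unknown))
      stop("no diffusion_spec supplied for medium: ",
           paste(unknown, collapse = ", "))
    vapply(records$medium,
           function(m) smoluchowski_rate(diffusion[[m]]), numeric(1))
  }
  out <- records
  out$delta_g_act_eff <- dga
  out$k_tst <- eyring_rate(dga, ctx, sigma = records$sigma,
                           kappa = records$kappa)
  out$k_d <- unname(k_d)
  out$k_app <- collins_kimball(out$k_tst, out$k_d)
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Branching ratios of parallel pathways
#'
#' The percentage contribution of each channel to the total rate of one
#' species in one medium: `gamma_i = 100 * k_i / sum(k)`.
#'
#' @param k Apparent rate constants of the parallel pathways (M^-1 s^-1), or
#'   a `rate_table` from [evaluate_rates()] whose `k_app` column is used.
#' @return Numeric vector of percentages summing to 100.
#' @export
branching_ratios <- function(k) {
  if (is.data.frame(k)) k <- k$k_app
  if (!length(k)) stop("need at least one pathway")
  if (any(k < 0)) stop("rate constants must be >= 0")
  tot <- sum(k)
  if (tot == 0) stop("branching ratios undefined: all rate constants are zero")
  100 * k / tot
}

#' Total rate constant of a species
#'
#' Arithmetic sum of the apparent rate constants of all parallel pathways of
#' one species in one medium.
#'
#' @inheritParams branching_ratios
#' @return The summed rate constant (0 for an empty set).
#' @export
total_rate <- function(k) {
  if (is.data.frame(k)) k <- k$k_app
  if (any(k < 0)) stop("rate constants must be >= 0")
  sum(k)
}

#' Molar-fraction-corrected and overall rate constants
#'
#' In aqueous solution the measurable rate constant of a polyprotic
#' antioxidant folds in the acid-base speciation of both partners: each
#' species' total rate is weighted by its own molar fraction and by the
#' fraction of the kinetically active (protonated) radical form,
#' \deqn{k_{corr,j} = f_j(pH)\, f_{rad}(pH)\, k_{total,j}, \qquad
#'       k_{overall} = \sum_j k_{corr,j}.}
#' In a lipid medium no speciation applies and the overall rate equals the
#' total rate.
#'
#' @param k_totals Named or ordered numeric vector of per-species total rate
#'   constants, one per ladder state (in ladder order).
#' @param ladder A [protonation_ladder()] for the antioxidant.
#' @param radical_pair A [radical_acid_base_pair()], or `NULL` when the
#'   partner has no acid-base equilibrium (radical factor 1).
#' @param ph The pH at which to evaluate the correction.
#' @param medium `"water"` (apply corrections) or `"lipid"` (bypass them; the
#'   single `k_totals` value is returned unchanged).
#' @return A list with `k_corrected` (named per species), `k_overall`,
#'   `fractions` and `radical_fraction`.
#' @export
corrected_overall <- function(k_totals, ladder, radical_pair = NULL, ph = 7.4,
                              medium = c("water", "lipid")) {
  medium <- match.arg(medium)
  if (medium == "lipid") {
    k <- sum(k_totals)
    return(list(k_corrected = k_totals, k_overall = k,
                fractions = rep(1, length(k_totals)), radical_fraction = 1))
  }
  stopifnot(inherits(ladder, "protonation_ladder"))
  if (length(k_totals) != length(ladder$labels))
    stop("need one k_total per ladder state (got ", length(k_totals),
         " for ", length(ladder$labels), " states)")
  f <- molar_fractions(ladder, ph)
  f_rad <- if (is.null(radical_pair)) 1 else active_fraction(radical_pair, ph)
  k_corr <- stats::setNames(as.numeric(k_totals) * f * f_rad, ladder$labels)
  list(k_corrected = k_corr, k_overall = sum(k_corr),
       fractions = f, radical_fraction = f_rad)
}

#' pH scan of the overall rate constant
#'
#' Evaluates [corrected_overall()] on a pH grid and reports the curve of
#' log10(k_overall) with per-species contributions, plus the location and
#' depth of its minimum. The default grid (1.5 to 8.5, step 0.01, inclusive
#' endpoints) spans gastric acidity to the mild alkalinity of the small
#' intestine.
#'
#' @inheritParams corrected_overall
#' @param ph_from,ph_to,ph_by Grid specification, within \[0, 14\].
#' @return An object of class `ph_scan`: a list with `grid` (data.frame of
#'   `ph`, `k_overall`, `log10_k`, one contribution column per species),
#'   `minimum` (list with `ph` and `log10_k`), `ladder` and `radical_pair`.
#' @export
ph_scan <- function(k_totals, ladder, radical_pair = NULL,
                    ph_from = 1.5, ph_to = 8.5, ph_by = 0.01) {
  stopifnot(ph_from >= 0, ph_to <= 14, ph_to > ph_from, ph_by > 0)
  grid <- seq(ph_from, ph_to, by = ph_by)
  if (!length(grid)) stop("empty pH grid")
  f <- molar_fractions(ladder, grid)
  if (is.null(dim(f))) f <- matrix(f, nrow = length(grid))
  f_rad <- if (is.null(radical_pair)) rep(1, length(grid))
           else active_fraction(radical_pair, grid)
  contrib <- sweep(f, 2, as.numeric(k_totals), `*`) * f_rad
  k_overall <- rowSums(contrib)
  out <- data.frame(ph = grid, k_overall = k_overall,
                    log10_k = log10(k_overall))
  colnames(contrib) <- paste0("k_", ladder$labels)
  out <- cbind(out, as.data.frame(contrib))
  i_min <- which.min(out$log10_k)
  structure(list(grid = out,
                 minimum = list(ph = out$ph[i_min],
                                log10_k = out$log10_k[i_min]),
                 ladder = ladder, radical_pair = radical_pair),
            class = "ph_scan")
}

#' @export
print.ph_scan <- function(x, ...) {
  cat(sprintf("<ph_scan> %d points, pH %.2f..%.2f\n", nrow(x$grid),
              min(x$grid$ph), max(x$grid$ph)))
  cat(sprintf("  minimum: log10(k) = %.3f at pH %.2f\n",
              x$minimum$log10_k, x$minimum$ph))
  invisible(x)
}

#' @export
plot.ph_scan <- function(x, ...) {
  grid <- x$grid
  sp_cols <- grep("^k_", names(grid), value = TRUE)
  graphics::plot(grid$ph, grid$log10_k, type = "l", lwd = 2,
                 xlab = "pH", ylab = expression(log[10](k[overall])), ...)
  for (i in seq_along(sp_cols))
    graphics::lines(grid$ph, log10(pmax(grid[[sp_cols[i]]], 1e-300)),
                    lty = i + 1, col = i + 1)
  graphics::legend("bottomright", legend = c("overall", sub("^k_", "", sp_cols)),
                   lty = c(1, seq_along(sp_cols) + 1),
                   col = c(1, seq_along(sp_cols) + 1), bty = "n")
  invisible(x)
}
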
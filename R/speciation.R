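#' Protonation ladder of a polyprotic antioxidant
#'
#' An ordered sequence of acid-base macro-states, from the most protonated to
#' the least, linked by successive acid dissociation constants. A ladder with
#' n states carries n - 1 pKa values. The ladder is the input to
#' [molar_fractions()], which evaluates the Henderson-Hasselbalch speciation
#' at any pH.
#'
#' @param labels Character vector of state labels, most protonated first
#'   (e.g. `c("H3Glg", "H2Glg-", "HGlg2-")`).
#' @param pkas Numeric vector of successive pKa values, `length(labels) - 1`.
#'   No monotonicity is assumed, but every value must be finite.
#' @return An object of class `protonation_ladder`.
#' @seealso [molar_fractions()], [galangin_constants()]
#' @export
protonation_ladder <- function(labels, pkas) {
  labels <- as.character(labels)
  pkas <- as.numeric(pkas)
  if (length(labels) != length(pkas) + 1L)
    stop("ladder mismatch: need length(labels) == length(pkas) + 1 (got ",
         length(labels), " labels, ", length(pkas), " pKa values)")
  if (length(labels) < 1L) stop("ladder needs at least one state")
  if (anyNA(pkas) || any(!is.finite(pkas))) stop("all pKa values must be finite")
  structure(list(labels = labels, pkas = pkas), class = "protonation_ladder")
}

#' @export
print.protonation_ladder <- function(x, ...) {
  cat("<protonation_ladder> ", paste(x$labels, collapse = " -> "), "\n")
  if (length(x$pkas)) cat("  pKa:", paste(format(x$pkas), collapse = ", "), "\n")
  invisible(x)
}

#' Acid-base pair of a radical partner
#'
#' The reacting radical may itself sit in an acid-base equilibrium (for the
#' hydroperoxyl radical, •OOH/O2•- with pKa 4.8); only the protonated form is
#' taken as kinetically relevant for the scavenging chemistry, so overall rate
#' constants are scaled by its molar fraction.
#'
#' @param protonated_label,deprotonated_label Text labels of the two forms.
#' @param pka The dissociation constant of the pair (dimensionless, finite).
#' @return An object of class `radical_acid_base_pair`.
#' @export
radical_acid_base_pair <- function(protonated_label, deprotonated_label, pka) {
  stopifnot(length(pka) == 1L)
  if (!is.finite(pka)) stop("pka must be finite")
  structure(list(protonated_label = as.character(protonated_label),
                 deprotonated_label = as.character(deprotonated_label),
                 pka = as.numeric(pka)),
            class = "radical_acid_base_pair")
}

#' Molar fractions of every protonation state at a given pH
#'
#' Closed-form Henderson-Hasselbalch speciation: the unnormalized weight of
#' state j (0-based, counting deprotonations) is 10^(j*pH - sum of the first j
#' pKa values); fractions are these weights normalized to 1. Weights are
#' evaluated in log10 space relative to the largest exponent, so ladders and
#' pH values far from any pKa do not overflow. No fraction is ever floored or
#' zeroed: states with tiny populations can still dominate the kinetics when
#' their rate constants are large.
#'
#' @param ladder A [protonation_ladder].
#' @param ph pH value(s), finite. Vectorized over `ph`.
#' @return For scalar `ph`, a named numeric vector of fractions (one per
#'   state, summing to 1). For vector `ph`, a matrix with one row per pH and
#'   one named column per state.
#' @examples
#' molar_fractions(protonation_ladder(c("HA", "A-"), 4.8), 7.4)  # c(0.0025, 0.9975)
#' @export
molar_fractions <- function(ladder, ph) {
  stopifnot(inherits(ladder, "protonation_ladder"))
  if (!is.numeric(ph) || anyNA(ph) || any(!is.finite(ph)))
    stop("ph must be finite numeric")
  cum <- c(0, cumsum(ladder$pkas))          # sum of first j pKa values
  j <- seq_along(ladder$labels) - 1L
  one <- function(p) {
    expo <- j * p - cum                     # log10 weights
    w <- 10^(expo - max(expo))
    w / sum(w)
  }
  if (length(ph) == 1L) {
    stats::setNames(one(ph), ladder$labels)
  } else {
    res <- vapply(ph, one, numeric(length(j)))
    out <- if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
    colnames(out) <- ladder$labels
    rownames(out) <- NULL
    out
  }
}

#' Fraction of the protonated (kinetically active) radical form
#'
#' Evaluates 1 / (1 + 10^(pH - pKa)) for a radical acid-base pair: the molar
#' fraction of the protonated form, which is the species considered the
#' primary contributor to oxidative damage.
#'
#' @param pair A [radical_acid_base_pair].
#' @param ph pH value(s), finite. Vectorized.
#' @return Numeric fraction(s) in (0, 1).
#' @examples
#' p <- radical_acid_base_pair("OOH", "O2-", 4.8)
#' active_fraction(p, 7.4)   # 0.0025
#' @export
active_fraction <- function(pair, ph) {
  stopifnot(inherits(pair, "radical_acid_base_pair"))
  if (!is.numeric(ph) || anyNA(ph) || any(!is.finite(ph)))
    stop("ph must be finite numeric")
  1 / (1 + 10^(ph - pair$pka))
}

#' Read a speciation configuration from YAML or JSON
#'
#' Loads a ladder and (optionally) a radical acid-base pair from a config
#' file, so systems other than the bundled galangin set can be described
#' without touching code. Expected top-level keys: `ladder` (with `labels`
#' and `pkas`) and optionally `radical_pair` (with `protonated`,
#' `deprotonated`, `pka`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `ladder` and (if present) `radical_pair`.
#' @export
read_speciation_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$ladder)) stop("config must contain a 'ladder' entry")
  out <- list(ladder = protonation_ladder(cfg$ladder$labels,
                                          as.numeric(cfg$ladder$pkas)))
  if (!is.null(cfg$radical_pair)) {
    rp <- cfg$radical_pair
    out$radical_pair <- radical_acid_base_pair(rp$protonated, rp$deprotonated,
                                               as.numeric(rp$pka))
  }
  out
}
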
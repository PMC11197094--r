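#' Load a bundled galangin reference dataset
#'
#' The package ships the curated energetics of the galangin benchmark system
#' as plain-text fixtures: hydroperoxyl-scavenging pathways and their
#' aggregates (`"table1"`), Cu(II) reduction by physiological reductants for
#' the free ion and each complex (`"table3"`), electron-transfer scavenging
#' of the hydroxyl radical by the complexes (`"table4"`), repair pathways for
#' oxidized biomolecule models and their per-species aggregates (`"table5"`),
#' superoxide-mediated regeneration steps (`"table6"`), and the scalar
#' constants quoted in the accompanying analyses (`"text_constants"`).
#' All numeric cells are stored at their published precision (3 significant
#' figures for rate constants, 1 decimal for energies); rows known to be
#' inconsistent with the rest of their table carry a non-empty `note`.
#'
#' @param table_id One of `"table1"`, `"table3"`, `"table4"`, `"table5"`,
#'   `"table6"`, `"text_constants"`.
#' @return For `"table1"` and `"table5"`, a list with `pathways` and
#'   `totals` data.frames; for `"table3"`, `"table4"`, `"table6"` a
#'   data.frame; for `"text_constants"` a named list.
#' @export
load_fixture <- function(table_id) {
  ids <- c("table1", "table3", "table4", "table5", "table6", "text_constants")
  if (!is.character(table_id) || length(table_id) != 1L || !table_id %in% ids)
    stop("unknown fixture id; must be one of: ", paste(ids, collapse = ", "))
  ext <- function(f) system.file("extdata", f, package = "radscav",
                                 mustWork = TRUE)
  rd <- function(f) utils::read.csv(ext(f), stringsAsFactors = FALSE)
  switch(table_id,
    table1 = list(pathways = pathway_table(rd("table1_pathways.csv")),
                  totals = rd("table1_totals.csv")),
    table3 = rd("table3_prooxidant.csv"),
    table4 = rd("table4_oil2_set.csv"),
    table5 = list(pathways = rd("table5_repair_pathways.csv"),
                  totals = rd("table5_repair_totals.csv")),
    table6 = rd("table6_regeneration.csv"),
    text_constants = .text_constants())
}

.text_constants <- function() {
  list(
    radical_pka = 4.8,            # •OOH / O2•- acid-base pair
    dg_threshold = 10.0,          # kcal/mol endergonicity screen
    media = c("lipid", "water"),
    ph_physiological = 7.4,
    k_overall_lipid = 3.77e3,     # M^-1 s^-1, pentyl ethanoate
    k_overall_water = 6.21e4,     # M^-1 s^-1, pH 7.4
    log_k_minimum = 3.52,         # depth of the pH-scan basin
    # reaction free energies quoted for the scavenging thermochemistry
    thermo_dg = list(
      lipid_fhat_c3 = -0.8, lipid_raf_c2 = -2.2,
      neutral_fhat_c3 = -3.5, neutral_raf_c2 = -3.5,
      monoanion_fhat_c3 = -7.1, monoanion_raf_c2 = -4.9,
      dianion_fhat = -4.9, dianion_raf_c2 = -18.2,
      set_neutral = 33.8, set_monoanion = 18.8, set_dianion = 6.0),
    marcus_apex_dg = -25.0,       # kcal/mol, apex location quoted for SET
    chelation_two_state = list(ddg = 1.03, fractions = c(0.85, 0.15)),
    oil2_coordinated_water_dg = 3.0,
    lm_repair_dg = c(C3 = 11.4, C5 = 24.3, C7 = 20.8))
}

#' Parse a rate constant printed in scientific notation
#'
#' Normalizes the typeset forms found in published kinetics tables -
#' `"2.50 × 10^9"`, `"6.51 x 10^-2"`, Unicode minus signs and en-dashes -
#' to plain doubles. Plain numeric strings pass through unchanged.
#'
#' @param x Character vector of printed numbers.
#' @return Numeric vector; unparseable entries yield `NA` with a warning.
#' @export
parse_printed_number <- function(x) {
  s <- as.character(x)
  s <- gsub("−|–", "-", s)                 # minus sign, en-dash
  s <- gsub("\\s", " ", s)
  m <- regmatches(s, regexec(
    "^ *([+-]?[0-9]*\\.?[0-9]+) *[x×] *10\\^?\\(?([+-]?[0-9]+)\\)? *$", s))
  out <- vapply(seq_along(s), function(i) {
    if (length(m[[i]]) == 3L) {
      as.numeric(paste0(m[[i]][2], "e", m[[i]][3]))
    } else {
      suppressWarnings(as.numeric(s[i]))
    }
  }, numeric(1))
  if (anyNA(out) && !all(is.na(x) | trimws(as.character(x)) %in% c("", "NA")))
    warning("some entries could not be parsed: ",
            paste(utils::head(s[is.na(out)], 3), collapse = "; "))
  out
}

#' Read a pathway table from a delimited file
#'
#' Reads a CSV (or other single-character-delimited) pathway file, validates
#' the header against the pathway schema, parses printed scientific notation
#' in the energy and rate columns, and reports malformed rows by line number.
#' Unknown columns are preserved.
#'
#' @param path File path.
#' @param sep Field separator, default `","`.
#' @return A [pathway_table()].
#' @export
read_pathways <- function(path, sep = ",") {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("species", "mechanism", "site", "medium")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("pathway file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  numcols <- intersect(c("delta_g", "delta_g_act", "lamda", "kappa", "sigma", "k"),
                       names(df))
  for (col in numcols) {
    raw <- df[[col]]
    val <- suppressWarnings(parse_printed_number(raw))
    bad <- is.na(val) & !(is.na(raw) | trimws(raw) %in% c("", "NA"))
    if (any(bad))
      stop("malformed numeric value(s) in column '", col, "' at line(s) ",
           paste(which(bad) + 1L, collapse = ", "), " of ", path)
    df[[col]] <- val
  }
  pathway_table(df)
}

#' Write a pathway table to a delimited file
#'
#' Numeric columns are serialized with 17 significant digits so that
#' `read_pathways(write_pathways(x))` round-trips at full double precision.
#'
#' @param records A [pathway_table()] or coercible data.frame.
#' @param path Output file path.
#' @param sep Field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_pathways <- function(records, path, sep = ",") {
  df <- as.data.frame(pathway_table(records))
  for (col in names(df))
    if (is.numeric(df[[col]]))
      df[[col]] <- ifelse(is.na(df[[col]]), NA, sprintf("%.17g", df[[col]]))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     na = "NA")
  invisible(path)
}

#' Configuration for the synthetic pathway-ensemble generator
#'
#' Describes the distributions a synthetic ensemble is drawn from. The
#' defaults emulate the energetic landscape of a deprotonatable flavonoid
#' reacting with small oxygen radicals: reaction free energies centered
#' mildly exergonic with a wide spread, reorganization energies spanning the
#' 9-43 kcal/mol range observed for such systems, and hydrogen-transfer
#' barriers offset ~17 kcal/mol above the driving force.
#'
#' @param n_species Number of antioxidant species. Default 3.
#' @param n_pathways_per_species Channels per species. Default 8.
#' @param dg_mean,dg_sd Normal distribution of reaction free energies
#'   (kcal/mol). Defaults -5 and 10.
#' @param lamda_range Uniform range for SET reorganization energies
#'   (kcal/mol). Default `c(9, 43)`.
#' @param dgact_noise_sd Gaussian noise added to generated barriers
#'   (kcal/mol). Default 0 (noise-free).
#' @param hat_offset Offset of hydrogen-transfer/adduct barriers above the
#'   reaction free energy (kcal/mol). Default 17.
#' @param inverted_region_fraction Fraction of SET channels forced into the
#'   Marcus inverted region (delta_g < -lamda). Default 0.
#' @param seed Integer RNG seed; the ensemble is reproducible for a fixed
#'   seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 3, n_pathways_per_species = 8,
                             dg_mean = -5, dg_sd = 10,
                             lamda_range = c(9, 43),
                             dgact_noise_sd = 0, hat_offset = 17,
                             inverted_region_fraction = 0, seed = 1L) {
  if (n_species < 1 || n_pathways_per_species < 1)
    stop("need at least one species and one pathway")
  if (dg_sd < 0 || dgact_noise_sd < 0) stop("standard deviations must be >= 0")
  if (length(lamda_range) != 2L || any(lamda_range <= 0) ||
      diff(lamda_range) < 0)
    stop("lamda_range must be a positive, non-decreasing interval")
  if (inverted_region_fraction < 0 || inverted_region_fraction > 1)
    stop("inverted_region_fraction must be in [0, 1]")
  structure(list(n_species = n_species,
                 n_pathways_per_species = n_pathways_per_species,
                 dg_mean = dg_mean, dg_sd = dg_sd,
                 lamda_range = lamda_range,
                 dgact_noise_sd = dgact_noise_sd, hat_offset = hat_offset,
                 inverted_region_fraction = inverted_region_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic pathway ensemble
#'
#' Draws a reproducible ensemble of reaction channels from a
#' [synthetic_config()]: reaction free energies from the configured normal,
#' SET reorganization energies uniform on `lamda_range`, SET barriers from
#' the Marcus parabola plus optional noise, and hydrogen-transfer/adduct
#' barriers as `max(0, delta_g + hat_offset)` plus noise. The requested
#' fraction of SET channels is reflected into the inverted region
#' (`delta_g < -lamda`); with `inverted_region_fraction = 0` no channel ends
#' up there. The caller's RNG state is left untouched.
#'
#' @param config A [synthetic_config()].
#' @return A [pathway_table()] with the generated columns plus `k` left
#'   unset; mechanisms are assigned round-robin as SET/fHAT/RAF.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  n <- config$n_species * config$n_pathways_per_species
  species <- rep(sprintf("S%02d", seq_len(config$n_species)),
                 each = config$n_pathways_per_species)
  mechanism <- rep_len(c("SET", "fHAT", "RAF"), n)
  site <- sprintf("site%d", rep_len(seq_len(config$n_pathways_per_species),
                                    n))
  dg <- stats::rnorm(n, config$dg_mean, config$dg_sd)
  lam <- ifelse(mechanism == "SET",
                stats::runif(n, config$lamda_range[1], config$lamda_range[2]),
                NA_real_)
  is_set <- mechanism == "SET"
  set_idx <- which(is_set)
  n_inv <- round(config$inverted_region_fraction * length(set_idx))
  inv <- set_idx[seq_len(n_inv)]
  normal_set <- setdiff(set_idx, inv)
  # reflect about -lamda so membership in the inverted region is exact
  refl <- function(i) -2 * lam[i] - dg[i]
  wrong_in <- normal_set[dg[normal_set] < -lam[normal_set]]
  dg[wrong_in] <- refl(wrong_in)
  wrong_out <- inv[dg[inv] >= -lam[inv]]
  dg[wrong_out] <- refl(wrong_out)
  dga <- numeric(n)
  dga[is_set] <- marcus_barrier(dg[is_set], lam[is_set])
  dga[!is_set] <- pmax(0, dg[!is_set] + config$hat_offset)
  if (config$dgact_noise_sd > 0)
    dga <- pmax(0, dga + stats::rnorm(n, 0, config$dgact_noise_sd))
  pathway_table(data.frame(
    species = species, mechanism = mechanism, site = site, medium = "water",
    delta_g = dg, delta_g_act = dga, lamda = lam, kappa = 1, sigma = 1,
    stringsAsFactors = FALSE))
}
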
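test_that("bundled fixtures load with stable structure and counts", {
  t1 <- load_fixture("table1")
  expect_s3_class(t1$pathways, "pathway_table")
  expect_equal(sum(t1$pathways$medium == "lipid"), 4)
  di <- t1$pathways[t1$pathways$species == "HGlg2-", ]
  expect_equal(nrow(di), 9)
  expect_true("SET" %in% di$mechanism)
  expect_setequal(di$site[di$mechanism == "RAF"],
                  c("C2", "C3", "C4", "C8", "C2'", "C4'", "C6'"))
  t6 <- load_fixture("table6")
  expect_equal(length(unique(t6$species)), 3)
  expect_true(all(tapply(t6$site_or_set, t6$species,
                         function(s) "SET" %in% s)))
  tc <- load_fixture("text_constants")
  expect_equal(tc$radical_pka, 4.8)
  expect_equal(tc$dg_threshold, 10.0)
  expect_setequal(tc$media, c("lipid", "water"))
  expect_error(load_fixture("table99"), "unknown fixture")
})

test_that("printed scientific notation is normalized to doubles", {
  expect_equal(parse_printed_number("2.50 × 10^9"), 2.50e9)
  expect_equal(parse_printed_number("6.51 x 10^-2"), 6.51e-2)
  expect_equal(parse_printed_number("5.89 × 10^–13"), 5.89e-13)
  expect_equal(parse_printed_number("–16.8"), -16.8)  # en-dash minus
  expect_equal(parse_printed_number("4.83"), 4.83)
  expect_warning(expect_true(is.na(parse_printed_number("ten"))), "parsed")
})

test_that("pathway files round-trip at full precision and report bad rows", {
  syn <- generate_synthetic(synthetic_config(seed = 9, dgact_noise_sd = 0.3))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_pathways(syn, path)
  back <- read_pathways(path)
  for (col in c("delta_g", "delta_g_act", "lamda", "kappa", "sigma"))
    expect_identical(back[[col]], syn[[col]])
  expect_identical(back$species, syn$species)
  # unknown columns survive the round trip
  syn$extra_note <- paste0("n", seq_len(nrow(syn)))
  write_pathways(syn, path)
  expect_identical(read_pathways(path)$extra_note, syn$extra_note)
  # a missing required column is reported by name
  df <- as.data.frame(syn)[, setdiff(names(syn), "mechanism")]
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_pathways(path), "mechanism")
  # malformed numeric cells are reported with their line number
  lines <- readLines(system.file("extdata", "table1_pathways.csv",
                                 package = "radscav"))
  lines[3] <- sub("19.8", "nineteen", lines[3], fixed = TRUE)
  writeLines(lines, path)
  expect_error(read_pathways(path), "line\\(s\\) 3")
})

test_that("synthetic ensembles are reproducible and respect the inverted region", {
  cfg <- synthetic_config(seed = 77, inverted_region_fraction = 0.5,
                          n_pathways_per_species = 30)
  a <- generate_synthetic(cfg)
  b <- generate_synthetic(cfg)
  expect_identical(a, b)
  set_rows <- a[a$mechanism == "SET", ]
  n_inv <- sum(set_rows$delta_g < -set_rows$lamda)
  expect_equal(n_inv, round(0.5 * nrow(set_rows)))
  none <- generate_synthetic(synthetic_config(seed = 77,
                                              n_pathways_per_species = 30))
  s0 <- none[none$mechanism == "SET", ]
  expect_false(any(s0$delta_g < -s0$lamda))
  # the generator leaves the caller's RNG stream untouched
  set.seed(5); x1 <- runif(1)
  set.seed(5); invisible(generate_synthetic(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("large synthetic ensembles match their generating distribution", {
  cfg <- synthetic_config(n_species = 10, n_pathways_per_species = 1000,
                          dg_mean = -5, dg_sd = 10,
                          inverted_region_fraction = 0, seed = 13)
  ens <- generate_synthetic(cfg)
  non_set <- ens$delta_g[ens$mechanism != "SET"]  # SET rows may be reflected
  se <- 10 / sqrt(length(non_set))
  expect_lt(abs(mean(non_set) - (-5)), 3 * se)
  expect_true(all(ens$lamda[ens$mechanism == "SET"] >= 9 &
                  ens$lamda[ens$mechanism == "SET"] <= 43))
})

test_that("noise-free synthetic barriers equal the Marcus pipeline exactly", {
  ens <- generate_synthetic(synthetic_config(seed = 21))
  s <- ens[ens$mechanism == "SET", ]
  expect_identical(s$delta_g_act, marcus_barrier(s$delta_g, s$lamda))
  # and evaluate_rates uses those barriers unchanged
  out <- evaluate_rates(ens)
  expect_identical(out$delta_g_act_eff, ens$delta_g_act)
})

test_that("degenerate synthetic configs are rejected", {
  expect_error(synthetic_config(n_species = 0), "at least one")
  expect_error(synthetic_config(dg_sd = -1), ">= 0")
  expect_error(synthetic_config(lamda_range = c(5, 2)), "interval")
  expect_error(synthetic_config(inverted_region_fraction = 1.5), "\\[0, 1\\]")
})
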
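test_that("equilibrium constants follow the free-energy exponential", {
  expect_equal(equilibrium_constant(0), 1)
  expect_equal(equilibrium_constant(-1.0277), 5.67, tolerance = 1e-3)
  # additivity over composed reactions
  expect_equal(equilibrium_constant(-2.3) * equilibrium_constant(1.1),
               equilibrium_constant(-1.2))
  # strictly decreasing in the free energy
  expect_true(all(diff(equilibrium_constant(seq(-5, 5, 0.5))) < 0))
})

test_that("apparent chelation constant combines pathway constants", {
  expect_equal(apparent_constant(5.67), 5.67)
  expect_equal(apparent_constant(c(5.67, 1.0)), 6.67)
  expect_gte(apparent_constant(c(2, 3, 4)), 4)  # never below the largest term
  expect_equal(apparent_constant(c(5.67, 1.0), method = "product"), 5.67)
  expect_error(apparent_constant(numeric(0)), "at least one")
})

test_that("Boltzmann populations reproduce the two-site chelation preference", {
  f <- boltzmann_fractions(c(0, 1.03))
  expect_equal(round(f, 2), c(0.85, 0.15))
  expect_equal(sum(f), 1)
  # a >= 4.1 kcal/mol gap leaves the preferred site essentially unitary
  expect_gt(boltzmann_fractions(c(0, 4.1))[1], 0.999)
  expect_equal(boltzmann_fractions(c(1, 1, 1)), rep(1 / 3, 3))
  # invariance under a constant energy shift
  set.seed(3)
  g <- rnorm(6, 0, 5)
  expect_equal(boltzmann_fractions(g), boltzmann_fractions(g + 123.4))
})

test_that("reduction kinetics reproduces the free-ion Marcus barriers", {
  red <- reduction_kinetics(-27.8, 38.7)    # free Cu(II) + superoxide
  expect_equal(round(red$delta_g_act, 1), 0.8)
  asc <- reduction_kinetics(-3.1, 33.4)     # free Cu(II) + ascorbate
  expect_equal(round(asc$delta_g_act, 1), 6.9)
  # a barrierless reduction runs at the diffusion limit
  bl <- reduction_kinetics(-30, 30)
  expect_equal(bl$k_app, bl$k_d, tolerance = 0.01)
  # partner fractions scale the final rate only
  half <- reduction_kinetics(-27.8, 38.7, reductant_fraction = 0.5)
  expect_equal(half$k, red$k / 2)
})

test_that("OIL-1 classification reproduces every tabulated direction", {
  t3 <- load_fixture("table3")
  ref <- t3[t3$stoichiometry == "free", ]
  cx <- t3[t3$stoichiometry != "free", ]
  cmp <- data.frame(
    complex_label = paste(cx$complex_label, cx$motif),
    reductant = cx$reductant, k_complex = cx$k,
    k_reference = ref$k[match(cx$reductant, ref$reductant)])
  out <- oil1_classify(cmp)
  expect_equal(out$direction, cx$direction)
  expect_true(all(out$fold_change >= 1))
  # the dianionic bis-complex inhibits reduction by both reductants
  expect_true(all(out$oil1_agent[out$complex_label == "[Cu(HGlg)2]^2- C3C4"]))
  # ascorbate reduction of the dianionic bis-complex is essentially shut off
  expect_gt(out$fold_change[out$complex_label == "[Cu(HGlg)2]^2- C3C4" &
                            out$reductant == "ascorbate"], 1e11)
  # a complex reduced faster than the free ion is not an OIL-1 agent
  expect_false(any(out$oil1_agent[out$complex_label ==
                                  "[Cu(H3Glg)(H2O)2]^2+ C3C4"]))
  # ties are conservatively classified down
  tie <- oil1_classify(data.frame(complex_label = "X", reductant = "r",
                                  k_complex = 2, k_reference = 2))
  expect_equal(tie$direction, "down")
  expect_equal(tie$fold_change, 1)
})

test_that("OIL-2 SET rates recover the tabulated barriers and plateau", {
  t4 <- load_fixture("table4")
  out <- oil2_set_rates(t4)
  expect_lt(max(abs(out$delta_g_act - t4$delta_g_act)), 0.15)
  # near-barrierless channels sit within 15% of the diffusion limit
  fast <- out$delta_g_act <= 0.5
  expect_true(all(rel_err(out$k_app[fast], out$k_d[fast]) < 0.15))
  # the strongly endergonic bis-complex channel is many orders slower
  expect_lt(out$k_app[out$delta_g == 19.0], 1)
})

test_that("thermochemical OIL-2 screen partitions and ranks sites", {
  dgmap <- data.frame(
    site = c("H2O", "C3", "C5", "C7", "C2"),
    mechanism = c("fHAT", "fHAT", "fHAT", "fHAT", "RAF"),
    delta_g = c(3.0, -33.0, -25.5, -9.4, -12.0))
  out <- oil2_thermo_screen(dgmap)
  expect_equal(out$classification[out$site == "H2O"], "endergonic")
  fhat <- out[out$mechanism == "fHAT", ]
  expect_equal(fhat$site[fhat$rank == 1], "C3")  # most exergonic donor site
  expect_false("k" %in% names(out))              # no rate constants emitted
  allneg <- oil2_thermo_screen(data.frame(site = c("a", "b"),
                                          mechanism = "RAF",
                                          delta_g = c(-1, -2)))
  expect_true(all(allneg$classification == "exergonic"))
})
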
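# Brute-force speciation oracle: build unnormalized weights from explicit
# concentrations ([H+] = 10^-pH, Ka_i = 10^-pKa_i) instead of the closed-form
# log10 expression used by the implementation.
oracle_fractions <- function(pkas, ph) {
  h <- 10^(-ph)
  ka <- 10^(-pkas)
  w <- numeric(length(pkas) + 1L)
  w[1] <- 1
  for (j in seq_along(pkas)) w[j + 1L] <- w[j] * ka[j] / h
  w / sum(w)
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

water_totals <- function() {
  t1 <- load_fixture("table1")
  with(t1$totals[t1$totals$medium == "water", ], setNames(k_total, species))
}
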
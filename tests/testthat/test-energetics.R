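test_that("relative energies are cis minus trans and need both fields", {
  pair <- isomer_pair("N0000", "gas",
                      trans = list(E = -333806.071, G = 0),
                      cis = list(E = -333801.441, G = 4.92))
  expect_equal(relative_energy(pair, "E"), 4.63)
  expect_equal(relative_energy(pair, "G"), 4.92)
  nog <- isomer_pair("N0000", "gas", trans = list(E = -1), cis = list(E = -1))
  expect_equal(relative_energy(nog, "E"), 0)
  expect_error(relative_energy(nog, "G"), "missing")
})

test_that("gas-phase cis destabilization recomputed from optE matches the printed column", {
  t5 <- amide_table(5)
  t9 <- amide_table(9)
  t7 <- amide_table(7)
  lab5 <- split_isomer_label(t5$compound)
  lab9 <- split_isomer_label(t9$compound)
  lab7 <- split_isomer_label(t7$compound)
  for (code in model_compound_codes()) {
    pair <- isomer_pair(code, "gas",
                        trans = list(E = t5$opt_e[lab5$code == code]),
                        cis = list(E = t9$opt_e[lab9$code == code]))
    expect_equal(relative_energy(pair, "E"), t7$d_e[lab7$code == code],
                 tolerance = 5e-3, label = code)
  }
})

test_that("solvation shifts are water-only, cis minus trans", {
  expect_equal(solvation_shift(-19.43, -16.33), -3.10)
  expect_equal(solvation_shift(-19.86, -11.16), -8.70)
  expect_equal(solvation_shift(-5, -5), 0)
  expect_error(solvation_shift(-19.43, -16.33, phase = "gas"), "water")

  # recomputed from the packaged tables (tables 6 and 8)
  t6 <- amide_table(6)
  t8 <- amide_table(8)
  shift <- solvation_shift(t8$solvation_e, t6$solvation_e)
  expect_equal(shift[split_isomer_label(t8$compound)$code == "N0000"], -3.10)
  # most cis isomers are better solvated than their trans counterparts
  expect_gte(sum(shift < 0), 8)
})

test_that("effective barriers select the minimum present free-energy entry", {
  entries <- data.frame(type = c("anti", "anti", "syn", "syn"),
                        direction = c("+", "-", "+", "-"),
                        dg = c(13.70, 13.72, 19.91, 19.84))
  bs <- effective_barrier(entries)
  expect_equal(bs$dg_eff, 13.70)
  expect_equal(bs$argmin, "anti+")

  single <- effective_barrier(data.frame(type = "syn", direction = "-", dg = 17.5))
  expect_equal(single$dg_eff, 17.5)
  expect_equal(single$argmin, "syn-")

  # absent entries are skipped; all-absent is an error
  with_na <- data.frame(type = c("anti", "syn"), direction = c("+", "+"),
                        dg = c(NA, 20.07))
  expect_equal(effective_barrier(with_na)$dg_eff, 20.07)
  expect_error(effective_barrier(data.frame(type = "syn", direction = "+",
                                            dg = NA_real_)), "no barrier entries")

  # tie: lexicographically first key, anti before syn, + before -
  tie <- data.frame(type = c("syn", "anti"), direction = c("+", "-"),
                    dg = c(10, 10))
  expect_equal(effective_barrier(tie)$argmin, "anti-")
})

test_that("effective barriers over the packaged tables match both printed columns", {
  for (n in c(11, 12)) {
    tab <- amide_table(n)
    summaries <- barrier_summaries(n)
    for (i in seq_len(nrow(tab))) {
      expect_equal(summaries[[tab$compound[i]]]$dg_eff, tab$dg_eff[i],
                   label = paste("table", n, tab$compound[i]))
    }
  }
  # the one compound where a syn path beats both anti paths (water)
  expect_equal(barrier_summaries(12)[["N011'0"]]$argmin, "syn+")
  expect_equal(barrier_summaries(12)[["N011'0"]]$dg_eff, 18.55)
  expect_equal(barrier_summaries(11)[["N0000"]]$argmin, "anti+")
})

test_that("dg_eff is a lower bound and robust to dropping non-argmin entries", {
  for (s in barrier_summaries(11)) {
    present <- is.finite(s$entries$dg)
    expect_true(all(s$dg_eff <= s$entries$dg[present]))
    key <- paste0(s$entries$type, s$entries$direction)
    non_argmin <- which(present & key != s$argmin)
    if (length(non_argmin) > 0) {
      drop_one <- s$entries[-non_argmin[length(non_argmin)], , drop = FALSE]
      expect_equal(effective_barrier(drop_one)$dg_eff, s$dg_eff)
    }
  }
})

test_that("equilibrium cis fraction is Boltzmann-consistent and monotone", {
  expect_equal(equilibrium_cis_fraction(0), 0.5)
  expect_lt(equilibrium_cis_fraction(50), 1e-20)

  # closed-form oracle evaluated independently
  dg <- 2.03
  rt <- 1.987204e-3 * 298.15
  expect_equal(equilibrium_cis_fraction(dg),
               exp(-dg / rt) / (1 + exp(-dg / rt)), tolerance = 1e-6)

  grid <- seq(-5, 10, by = 0.25)
  f <- equilibrium_cis_fraction(grid)
  expect_true(all(diff(f) < 0))
  expect_error(equilibrium_cis_fraction(1, temperature = 0), "positive")
})
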
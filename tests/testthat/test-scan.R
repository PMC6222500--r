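test_that("scan schedules must be strictly decreasing and positive", {
  expect_silent(scan_schedule(c(15, 2, 0.125)))
  expect_equal(scan_schedule_water()$steps, c(15, 2, 0.25))
  expect_error(scan_schedule(c(2, 15)), "decreasing")
  expect_error(scan_schedule(c(15, 15)), "decreasing")
  expect_error(scan_schedule(c(15, 0)), "decreasing|positive")
})

test_that("the driver locates the analytic cosine barrier in both directions", {
  b <- make_potential(data.frame(k = 2, v = 10, gamma = 0))
  p <- run_rcs(b, start = 180, direction = "+")
  e <- find_ebg(p)
  # + sweep from 180 tops out at omega = 270 (wrapped -90), height 10
  expect_lt(ang_diff(e$omega_star, 270), 0.125)
  expect_equal(e$e_star, 10, tolerance = 1e-6)
  expect_equal(p$start_isomer, "trans")

  e2 <- find_ebg(run_rcs(b, start = 180, direction = "-"))
  expect_lt(ang_diff(e2$omega_star, 90), 0.125)
  expect_equal(e2$e_star, 10, tolerance = 1e-6)

  # even symmetry: both directions agree
  expect_equal(e$e_star, e2$e_star, tolerance = 1e-6)
})

test_that("profiles are monotone along the scan and refinement never loses the peak", {
  b <- random_two_well(3)
  for (dd in c("+", "-")) {
    p <- run_rcs(b, ground_truth(b)$omega_min_trans, dd)
    expect_true(all(diff(p$points$s) > 0))
    sgn <- if (dd == "+") 1 else -1
    expect_true(all(sgn * diff(p$points$omega) > 0))
    expect_true(all(diff(p$round_estimates) >= -1e-9))
  }
})

test_that("scan preconditions and degenerate profiles raise errors", {
  b <- make_potential(data.frame(k = 2, v = 10, gamma = 0))
  expect_error(run_rcs(b, start = 100, direction = "+"), "not a local minimum")

  failing <- energy_backend(function(w) stop("SCF failed"), name = "failing")
  expect_error(run_rcs(failing, 180, "+"), "scan error at omega")

  flat <- energy_backend(function(w) rep(1, length(w)), name = "flat")
  expect_error(run_rcs(flat, 180, "+"), "no interior maximum")
})

test_that("syn/anti classification follows proximity to 60/120 with a syn tie-break", {
  expect_equal(classify_ebg(62)$type, "syn")
  expect_equal(classify_ebg(-118)$type, "anti")
  expect_equal(classify_ebg(-57)$type, "syn")
  expect_false(classify_ebg(62)$ambiguous)
  tie <- classify_ebg(90)
  expect_equal(tie$type, "syn")
  expect_true(tie$ambiguous)
  expect_true(classify_ebg(-90)$ambiguous)
  expect_true(classify_ebg(0)$ambiguous)
})

test_that("a seeded battery of potentials matches the dense-grid oracle", {
  # three-round refinement must land within the final step size of the
  # oracle argmax and within 0.01 kcal/mol of the oracle height, in both
  # directions from both wells, while respecting the evaluation budget
  n_eval_bound <- ceiling(180 / 15) + 2 * (2 * 15 / 2) + 2 * (2 * 2 / 0.125) + 10
  for (i in 1:20) {
    b <- random_two_well(i)
    gt <- ground_truth(b)
    for (iso in c("trans", "cis")) {
      start <- if (iso == "trans") gt$omega_min_trans else gt$omega_min_cis
      gcol <- if (iso == "trans") "direction_from_trans" else "direction_from_cis"
      for (dd in c("+", "-")) {
        p <- run_rcs(b, start, dd)
        e <- find_ebg(p)
        row <- gt$barriers[gt$barriers[[gcol]] == dd, ]
        href <- if (iso == "trans") row$height_vs_trans else row$height_vs_cis
        expect_lt(ang_diff(e$omega_star, row$omega_star), 0.125)
        expect_lt(abs(e$e_star - href), 0.01)
        expect_lte(p$n_eval, n_eval_bound)
      }
    }
  }
})

test_that("barrier sets assemble directional entries with trans re-referencing", {
  # symmetric backend: one direction scanned, mirrors absent
  b <- make_potential(data.frame(k = 2, v = 10, gamma = 0))
  bs <- barrier_set(b, symmetric = TRUE)
  expect_equal(nrow(bs), 4)
  expect_equal(sum(is.na(bs$e_star)), 2)
  expect_setequal(bs$direction[is.na(bs$e_star)], "-")
  done <- bs[!is.na(bs$e_star), ]
  expect_equal(done$e_star, c(10, 10), tolerance = 1e-6)
  expect_equal(done$e_rel_trans, c(10, 10), tolerance = 1e-6)

  # asymmetric backend: four entries, inequivalent directions, and
  # cis-start heights re-referenced by the well offset
  ba <- random_two_well(2)
  gta <- ground_truth(ba)
  bsa <- barrier_set(ba)
  expect_equal(nrow(bsa), 4)
  expect_true(all(is.finite(bsa$e_star)))
  syn_rows <- bsa[bsa$start_isomer == "trans", ]
  expect_gt(abs(syn_rows$e_star[1] - syn_rows$e_star[2]), 1e-3)
  offset <- gta$e_min_cis - gta$e_min_trans
  cis_rows <- bsa[bsa$start_isomer == "cis", ]
  expect_equal(cis_rows$e_rel_trans, cis_rows$e_star + offset, tolerance = 1e-6)

  # trans-start scans find the barriers the oracle places on each path
  for (r in seq_len(nrow(syn_rows))) {
    gt_row <- gta$barriers[gta$barriers$direction_from_trans == syn_rows$direction[r], ]
    expect_lt(ang_diff(syn_rows$omega_star[r], gt_row$omega_star), 0.125)
    expect_equal(syn_rows$e_star[r], gt_row$height_vs_trans, tolerance = 0.01)
  }
})

test_that("a surface can make one syn path cheaper than both anti paths", {
  # separate trans-start and cis-start surfaces emulate relaxation
  # hysteresis: the trans-start surface has a low barrier on its + path
  # near 60 degrees, the cis-start surface higher barriers near +/-120
  b_trans <- make_potential(
    data.frame(k = c(1, 2, 3), v = c(4, 14, 2.2), gamma = c(-15, 6, -24)),
    name = "trans-start surface")
  b_cis <- make_potential(
    data.frame(k = c(1, 2), v = c(2, 20), gamma = c(10, -4)),
    name = "cis-start surface")
  bs <- barrier_set(b_trans, b_cis)
  expect_true(all(is.finite(bs$e_rel_trans)))
  syn_min <- min(bs$e_rel_trans[bs$start_isomer == "trans"])
  anti_min <- min(bs$e_rel_trans[bs$start_isomer == "cis"])
  expect_lt(syn_min, anti_min)
})
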
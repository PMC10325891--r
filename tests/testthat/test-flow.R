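cal <- default_calibration()

test_that("fully open gates are the identity and pass fractions multiply", {
  ev <- simulate_population(cal, 2000, seed = 41)
  g <- gate_events(ev, gate_config(viability = 1, singlet = 1))
  expect_equal(nrow(g$events), nrow(ev))
  expect_equal(g$report$fraction, c(1, 1))

  g2 <- gate_events(ev, gate_config(viability = 0.9, singlet = 0.95))
  expect_equal(nrow(g2$events) / nrow(ev), prod(g2$report$fraction),
               tolerance = 1e-12)
  expect_lte(nrow(g2$events), nrow(ev))
})

test_that("density and band gates remove simulated debris and doublets", {
  mx <- population_mixture(debris_fraction = 0.10, doublet_fraction = 0.05)
  ev <- simulate_population(cal, 30000, seed = 42, mixture = mx)
  g <- gate_events(ev, gate_config(viability = 0.90, singlet = c(0.85, 1.10)))
  expect_equal(g$report$fraction[1], 0.90, tolerance = 0.02)
  expect_equal(g$report$fraction[2], 0.95, tolerance = 0.02)
  # ground-truth labels: survivors should be overwhelmingly viable singlets
  expect_lt(mean(g$events$class == "debris"), 0.05)
  expect_lt(mean(g$events$class == "doublet"), 0.005)
  expect_gt(mean(g$events$class == "cell"), 0.94)
  # most true viable singlets survive both gates
  expect_gt(sum(g$events$class == "cell") / sum(ev$class == "cell"), 0.9)
})

test_that("an explicit scatter polygon gates by point-in-polygon", {
  ev <- simulate_population(cal, 5000, seed = 43)
  poly <- cbind(c(5e4, 2e5, 2e5, 5e4), c(1e3, 1e3, 3e5, 3e5))
  g <- gate_events(ev, gate_config(viability = poly, singlet = NULL))
  inside <- ev$FSC_A > 5e4 & ev$FSC_A < 2e5 & ev$SSC_A > 1e3 & ev$SSC_A < 3e5
  expect_equal(nrow(g$events), sum(inside))
})

test_that("empty input yields empty output with a zeroed report", {
  g <- gate_events(simulate_population(cal, 0))
  expect_equal(nrow(g$events), 0)
  expect_equal(g$report$fraction, c(0, 0))
})

test_that("automatic BFP split recovers the infected fraction and truth labels", {
  lib <- make_library(1, 1, 0)
  eff <- effect_map(lib)
  n <- 20000
  assign <- rep(NA_character_, n)
  assign[seq_len(0.3 * n)] <- lib$sgRNA_id[1]
  ev <- simulate_population(cal, n, effects = eff, assignments = assign,
                            seed = 44)
  sp <- split_by_bfp(ev)
  expect_equal(nrow(sp$infected) / n, 0.30, tolerance = 0.02)
  # partition: union is the input, intersection empty
  expect_equal(nrow(sp$infected) + nrow(sp$uninfected), n)
  truth <- !is.na(ev$sgRNA)
  called <- ev$BFP > sp$threshold
  expect_gte(mean(called == truth), 0.99)
})

test_that("unimodal BFP is rejected in automatic mode, trivial split works", {
  ev <- simulate_population(cal, 5000, seed = 45)  # all uninfected
  expect_error(split_by_bfp(ev), "unimodal|threshold")
  sp <- split_by_bfp(ev, threshold = max(ev$BFP) + 1)
  expect_equal(nrow(sp$infected), 0)
  expect_equal(nrow(sp$uninfected), nrow(ev))
})

test_that("signed pseudo-log is odd, monotone, exactly invertible and unit-anchored", {
  d <- c(-1e6, -3.7, -1e-9, 0, 1e-9, 2.2, 1e6)
  s <- signed_log2(d, unit = 2)
  expect_equal(s, -signed_log2(-d, unit = 2))
  expect_true(all(diff(s) > 0))
  expect_equal(signed_log2_inverse(s, unit = 2), d, tolerance = 1e-12)
  # d = unit * (2^k - 1) maps to exactly k
  for (k in c(1, 3, 7.5)) expect_equal(signed_log2(3 * (2^k - 1), 3), k)
  expect_equal(signed_log2(0), 0)
})

test_that("reporter phenotype isolates GFP-specific effects with correct sign", {
  fcal <- flow_calibration()
  # identical populations: zero everything
  ev <- simulate_population(fcal, 3000, seed = 46)
  ph0 <- reporter_phenotype(ev, ev)
  expect_equal(ph0$dGFP, 0)
  expect_equal(ph0$dmCherry, 0)
  expect_equal(ph0$score, 0)

  up <- simulate_well(fcal, gfp_effect = 4, n = 4000, seed = 47)
  ph_up <- reporter_phenotype(up$infected, up$uninfected)
  expect_gt(ph_up$score, 0)
  down <- simulate_well(fcal, gfp_effect = 0.5, n = 4000, seed = 48)
  ph_down <- reporter_phenotype(down$infected, down$uninfected)
  expect_lt(ph_down$score, 0)

  expect_error(reporter_phenotype(ev[0, ], ev), "infected")
  expect_error(reporter_phenotype(ev, ev[0, ]), "uninfected")
})

test_that("population diagnostics reproduce trivial and scale-equivariant cases", {
  # constant ratio: ratio CV and boundary separation are zero
  n <- 1000
  set.seed(49)
  base <- rlnorm(n, 0, 0.5)
  ev <- data.frame(FSC_A = rep(1e5, n), FSC_H = rep(9.8e4, n),
                   SSC_A = rep(5e4, n), BFP = rep(50, n),
                   GFP = 2 * base, mCherry = base)
  d <- population_diagnostics(ev)
  expect_equal(d$ratio_cv, 0)
  expect_equal(d$boundary_separation_pct, 0)

  ev2 <- simulate_population(cal, 20000, seed = 50)
  d1 <- population_diagnostics(ev2)
  ev3 <- ev2
  ev3$GFP <- 7 * ev3$GFP; ev3$mCherry <- 7 * ev3$mCherry
  d2 <- population_diagnostics(ev3)
  expect_equal(d2$ratio_cv, d1$ratio_cv, tolerance = 1e-12)
  expect_equal(d2$correlation, d1$correlation, tolerance = 1e-12)
  expect_equal(d2$boundary_separation_pct, d1$boundary_separation_pct,
               tolerance = 1e-12)
  expect_error(population_diagnostics(ev2[1:2, ]), "3 events")
})

test_that("tail-boundary separation widens monotonically with intrinsic noise", {
  seps <- sapply(c(0.05, 0.15, 0.3, 0.5), function(sd_im) {
    calx <- reporter_calibration(extrinsic_sd_log = 0.5,
                                 intrinsic_sd_log_gfp = 0,
                                 intrinsic_sd_log_mcherry = sd_im)
    ev <- simulate_population(calx, 30000, seed = 51)
    population_diagnostics(ev)$boundary_separation_pct
  })
  expect_true(all(diff(seps) > 0))
})
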
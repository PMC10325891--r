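cal <- default_calibration()

test_that("population simulation is seed-deterministic and seed-sensitive", {
  a <- simulate_population(cal, 500, seed = 3)
  b <- simulate_population(cal, 500, seed = 3)
  c <- simulate_population(cal, 500, seed = 4)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$GFP, c$GFP)))
})

test_that("empty population returns a zero-row table with the full header", {
  ev <- simulate_population(cal, 0)
  expect_equal(nrow(ev), 0)
  expect_true(all(c("FSC_A", "FSC_H", "SSC_A", "BFP", "GFP", "mCherry",
                    "well", "sgRNA", "class") %in% names(ev)))
})

test_that("null effects leave infected and uninfected mCherry indistinguishable", {
  lib <- make_library(2, 5, 10)
  eff <- effect_map(lib)
  n <- 20000
  assign <- rep(NA_character_, n)
  assign[1:(n / 2)] <- sample(lib$sgRNA_id, n / 2, replace = TRUE)
  ev <- simulate_population(cal, n, effects = eff, assignments = assign,
                            seed = 5)
  inf <- !is.na(ev$sgRNA)
  se <- sqrt(var(ev$mCherry[inf]) / sum(inf) +
               var(ev$mCherry[!inf]) / sum(!inf))
  expect_lt(abs(mean(ev$mCherry[inf]) - mean(ev$mCherry[!inf])), 4 * se)
})

test_that("a 4-fold GFP effect quadruples the background-subtracted GFP mean", {
  lib <- make_library(1, 1, 0)
  eff <- effect_map(lib, gfp_effect = structure(4, names = lib$sgRNA_id[1]))
  n <- 40000
  on <- simulate_population(cal, n, effects = eff,
                            assignments = rep(lib$sgRNA_id[1], n), seed = 6)
  off <- simulate_population(cal, n, seed = 7)
  num <- mean(on$GFP) - cal$autofluorescence_gfp
  den <- mean(off$GFP) - cal$autofluorescence_gfp
  se_rel <- sqrt(var(on$GFP) / n / num^2 + var(off$GFP) / n / den^2)
  expect_lt(abs(num / den - 4), 4 * 4 * se_rel)
})

test_that("unknown sgRNA labels in assignments are reported", {
  lib <- make_library(1, 2, 0)
  eff <- effect_map(lib)
  expect_error(
    simulate_population(cal, 3, effects = eff,
                        assignments = c(lib$sgRNA_id[1], "bogus_sg", NA)),
    "bogus_sg")
})

test_that("sorted tails hold exactly floor(N * tail_fraction) events each", {
  lib <- make_library(5, 5, 50)
  cts <- simulate_screen(lib, NULL, cal, screen_design(coverage = 40, seed = 8))
  for (d in attr(cts, "diagnostics")) {
    expect_equal(d$tail_size, floor(d$n_bfp_pos * 0.15))
    expect_lte(2 * d$tail_size, d$n_bfp_pos)
  }
})

test_that("an all-non-targeting screen centres log2 tail ratios on zero", {
  lib <- make_library(0, 5, 60)
  cts <- simulate_screen(lib, NULL, cal, screen_design(coverage = 60, seed = 9))
  lr <- log2((cts$rep1_high + 1) / (cts$rep1_low + 1))
  expect_lt(abs(mean(lr)), 3 * sd(lr) / sqrt(length(lr)))
})

test_that("a strong GFP-effect sgRNA enriches in the high tail of every replicate", {
  lib <- make_library(10, 5, 50)
  sg <- lib$sgRNA_id[1]
  eff <- effect_map(lib, gfp_effect = structure(8, names = sg))
  cts <- simulate_screen(lib, eff, cal, screen_design(coverage = 60, seed = 10))
  row <- cts[cts$sgRNA_id == sg, ]
  expect_gt(row$rep1_high, row$rep1_low)
  expect_gt(row$rep2_high, row$rep2_low)
})

test_that("undersampled tails are rejected", {
  lib <- make_library(1, 5, 10)
  des <- screen_design(cells_per_replicate = 5, reads_per_sample = 100,
                       seed = 1)
  expect_error(simulate_screen(lib, NULL, cal, des), "undersampled")
})

test_that("null screens give sign-symmetric per-sgRNA log2 tail ratios", {
  # sign test pooled over 50 independent small all-null screens
  lib <- make_library(0, 5, 30)
  signs <- integer(0)
  for (s in 1:50) {
    des <- screen_design(tail_fraction = 0.15, replicates = 1, coverage = 30,
                         seed = 100 + s)
    cts <- simulate_screen(lib, NULL, cal, des)
    lr <- log2((cts$rep1_high + 1) / (cts$rep1_low + 1))
    signs <- c(signs, sign(lr[lr != 0]))
  }
  p <- binom.test(sum(signs > 0), length(signs))$p.value
  expect_gt(p, 0.01)
})

test_that("replicates are independent cohorts", {
  lib <- make_library(0, 5, 100)
  cts <- simulate_screen(lib, NULL, cal, screen_design(coverage = 50, seed = 12))
  lr1 <- log2((cts$rep1_high + 1) / (cts$rep1_low + 1))
  lr2 <- log2((cts$rep2_high + 1) / (cts$rep2_low + 1))
  expect_lt(abs(cor(lr1, lr2)), 0.3)
})

test_that("profile simulation matches its contract", {
  z <- simulate_profiles(12, 30, seed = 1)
  expect_equal(dim(z), c(12, 30))
  # pure noise: standard normal entries
  expect_equal(mean(z), 0, tolerance = 4 / sqrt(length(z)))
  expect_equal(sd(z), 1, tolerance = 0.08)
  spec <- list(list(perturbations = 1:4, genes = 1:10, effect = 5),
               list(perturbations = 5:8, genes = 11:20, effect = 5))
  z2 <- simulate_profiles(12, 30, spec, seed = 2)
  expect_equal(attr(z2, "row_clusters"), rep(c(1, 2, 0), c(4, 4, 4)))
  expect_equal(mean(z2[1:4, 1:10]), 5, tolerance = 0.5)
  bad <- list(list(perturbations = 1:4, genes = 1:5, effect = 1),
              list(perturbations = 4:6, genes = 6:9, effect = 1))
  expect_error(simulate_profiles(12, 30, bad), "overlapping")
})

test_that("derived seeds are stable, distinct and within integer range", {
  expect_identical(derive_seed(1, "screen", 1), derive_seed(1, "screen", 1))
  expect_false(derive_seed(1, "screen", 1) == derive_seed(1, "screen", 2))
  expect_false(derive_seed(1, "screen", 1) == derive_seed(2, "screen", 1))
  s <- derive_seed(2147483646, "reads", 99)
  expect_true(s >= 0 && s < 2^31)
})
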
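# shared fixtures built in code

# count table with explicit per-replicate tail counts
counts_table <- function(sgRNA_id, gene, ...) {
  reps <- list(...)
  df <- data.frame(sgRNA_id = sgRNA_id, gene = gene, stringsAsFactors = FALSE)
  for (nm in names(reps)) df[[nm]] <- as.integer(reps[[nm]])
  class(df) <- c("screen_counts", "data.frame")
  df
}

# calibration with GFP signal and mCherry on comparable scales, so that
# well-level reporter scores are not dominated by mCherry sampling noise
flow_calibration <- function(extrinsic = 0.3, intr_g = 0.05, intr_m = 0.15) {
  reporter_calibration(mean_AUG_gfp = 55200,
                       autofluorescence_gfp = 5,
                       mean_mcherry = 60,
                       extrinsic_sd_log = extrinsic,
                       intrinsic_sd_log_gfp = intr_g,
                       intrinsic_sd_log_mcherry = intr_m)
}

# internally controlled well: infected cells carrying one sgRNA plus
# uninfected cells, returned as (infected, uninfected) event tables
simulate_well <- function(cal, gfp_effect, mcherry_effect = 1, n = 2000,
                          seed = 1) {
  lib <- data.frame(sgRNA_id = "sgX", gene = "geneX",
                    stringsAsFactors = FALSE)
  eff <- effect_map(as_sgrna_library(lib),
                    gfp_effect = c(sgX = gfp_effect),
                    mcherry_effect = c(sgX = mcherry_effect))
  inf <- simulate_population(cal, n, effects = eff,
                             assignments = rep("sgX", n), seed = seed)
  uninf <- simulate_population(cal, n, seed = seed + 1)
  list(infected = inf, uninfected = uninf)
}

# adjusted Rand index between two labelings (closed-form contingency version)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
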
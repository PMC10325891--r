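#' Scatter/expression mixture parameters for simulated flow events
#'
#' Describes the event mixture a cytometer sees: viable single cells,
#' low-scatter debris, and doublets (two cells measured as one event, with
#' summed fluorescence and a depressed FSC-H/FSC-A ratio). Also holds the
#' BFP levels separating sgRNA-carrying (infected) from uninfected cells.
#'
#' @param debris_fraction,doublet_fraction event-class fractions; the
#'   remainder are viable singlets. Default 0 (clean population).
#' @param fsc_mean,fsc_sd_log,ssc_mean,ssc_sd_log lognormal scatter of
#'   viable cells.
#' @param singlet_ratio_mean,singlet_ratio_sd FSC-H/FSC-A ratio of singlets.
#' @param doublet_ratio_mean,doublet_ratio_sd FSC-H/FSC-A ratio of doublets.
#' @param debris_fsc_mean,debris_fsc_sd_log,debris_ssc_mean,debris_ssc_sd_log
#'   lognormal scatter of debris.
#' @param bfp_infected_mean,bfp_uninfected_mean,bfp_sd_log lognormal BFP
#'   levels (default 100-fold separation).
#' @return a classed list `population_mixture`.
#' @export
population_mixture <- function(debris_fraction = 0, doublet_fraction = 0,
                               fsc_mean = 1e5, fsc_sd_log = 0.12,
                               ssc_mean = 5e4, ssc_sd_log = 0.30,
                               singlet_ratio_mean = 0.98,
                               singlet_ratio_sd = 0.015,
                               doublet_ratio_mean = 0.55,
                               doublet_ratio_sd = 0.05,
                               debris_fsc_mean = 1.5e4,
                               debris_fsc_sd_log = 0.35,
                               debris_ssc_mean = 6e4,
                               debris_ssc_sd_log = 0.5,
                               bfp_infected_mean = 5000,
                               bfp_uninfected_mean = 50,
                               bfp_sd_log = 0.35) {
  stopifnot(debris_fraction >= 0, doublet_fraction >= 0,
            debris_fraction + doublet_fraction < 1)
  structure(as.list(environment()), class = "population_mixture")
}

flow_event_columns <- c("FSC_A", "FSC_H", "SSC_A", "BFP", "GFP", "mCherry",
                        "well", "sgRNA", "class")

empty_flow_events <- function() {
  data.frame(FSC_A = numeric(0), FSC_H = numeric(0), SSC_A = numeric(0),
             BFP = numeric(0), GFP = numeric(0), mCherry = numeric(0),
             well = character(0), sgRNA = character(0), class = character(0),
             stringsAsFactors = FALSE)
}

#' Simulate a reporter cell population as flow-cytometry events
#'
#' Draws per-event fluorescence under the shared-factor lognormal model:
#' each cell receives one extrinsic factor (cell state, size, integration
#' site) common to both channels and channel-specific intrinsic factors, all
#' mean-one lognormal. GFP is the codon-dependent reporter signal plus a
#' constant autofluorescence background; mCherry is the IRES-driven control.
#' sgRNA effects act multiplicatively on the GFP initiation term and/or on
#' mCherry, each expressed in a `penetrance` fraction of assigned cells.
#' Scatter channels and BFP come from the `mixture`; doublets carry doubled
#' fluorescence and a depressed FSC-H/FSC-A ratio, debris carries background
#' fluorescence only.
#'
#' @param calibration a [reporter_calibration()].
#' @param n_cells number of events to draw.
#' @param codon reporter start codon (must be in the calibration's
#'   `codon_efficiency`).
#' @param effects an [effect_map()], required when `assignments` is given.
#' @param assignments character vector (length `n_cells`) of sgRNA ids, with
#'   `NA` for uninfected cells; `NULL` for an uninfected reporter population.
#' @param seed RNG seed (integer).
#' @param mixture a [population_mixture()].
#' @param well optional well label stored on every event.
#' @return a data.frame of events with columns `FSC_A`, `FSC_H`, `SSC_A`,
#'   `BFP`, `GFP`, `mCherry`, `well`, `sgRNA` and the ground-truth `class`
#'   (`"cell"`, `"debris"` or `"doublet"`).
#' @export
simulate_population <- function(calibration, n_cells, codon = "CUG",
                                effects = NULL, assignments = NULL, seed = 1,
                                mixture = population_mixture(),
                                well = NA_character_) {
  stopifnot(inherits(calibration, "reporter_calibration"), n_cells >= 0)
  if (!codon %in% names(calibration$codon_efficiency))
    stop("unknown reporter codon: ", codon)
  if (n_cells == 0) return(empty_flow_events())
  if (!is.null(assignments)) {
    if (length(assignments) != n_cells)
      stop("assignments must have length n_cells")
    if (is.null(effects))
      stop("assignments require an effect_map")
    bad <- setdiff(unique(assignments[!is.na(assignments)]), effects$sgRNA_id)
    if (length(bad))
      stop("unknown sgRNA labels in assignments: ",
           paste(bad, collapse = ", "))
  } else {
    assignments <- rep(NA_character_, n_cells)
  }

  set.seed(as.integer(seed) %% 2147483647L)
  mx <- mixture
  cls <- sample(c("debris", "doublet", "cell"), n_cells, replace = TRUE,
                prob = c(mx$debris_fraction, mx$doublet_fraction,
                         1 - mx$debris_fraction - mx$doublet_fraction))

  # fluorescence of the underlying single cell
  s  <- calibration$extrinsic_sd_log
  ig <- calibration$intrinsic_sd_log_gfp
  im <- calibration$intrinsic_sd_log_mcherry
  extr <- stats::rlnorm(n_cells, -s^2 / 2, s)
  intg <- stats::rlnorm(n_cells, -ig^2 / 2, ig)
  intm <- stats::rlnorm(n_cells, -im^2 / 2, im)

  gfp_eff <- rep(1, n_cells)
  mch_eff <- rep(1, n_cells)
  infected <- !is.na(assignments)
  if (any(infected)) {
    idx <- match(assignments[infected], effects$sgRNA_id)
    expressed <- stats::runif(sum(infected)) < effects$penetrance[idx]
    ge <- ifelse(expressed, effects$gfp_effect[idx], 1)
    me <- ifelse(expressed, effects$mcherry_effect[idx], 1)
    gfp_eff[infected] <- ge
    mch_eff[infected] <- me
  }

  mu_s <- calibration$mean_AUG_gfp * calibration$codon_efficiency[[codon]]
  auto <- calibration$autofluorescence_gfp
  gfp_signal <- mu_s * extr * intg * gfp_eff
  gfp <- auto + gfp_signal
  mch <- calibration$mean_mcherry * extr * intm * mch_eff

  bfp <- ifelse(infected,
                stats::rlnorm(n_cells, log(mx$bfp_infected_mean), mx$bfp_sd_log),
                stats::rlnorm(n_cells, log(mx$bfp_uninfected_mean), mx$bfp_sd_log))

  # scatter
  fsc <- stats::rlnorm(n_cells, log(mx$fsc_mean), mx$fsc_sd_log)
  ssc <- stats::rlnorm(n_cells, log(mx$ssc_mean), mx$ssc_sd_log)
  ratio <- stats::rnorm(n_cells, mx$singlet_ratio_mean, mx$singlet_ratio_sd)

  is_debris <- cls == "debris"
  if (any(is_debris)) {
    nd <- sum(is_debris)
    fsc[is_debris] <- stats::rlnorm(nd, log(mx$debris_fsc_mean),
                                    mx$debris_fsc_sd_log)
    ssc[is_debris] <- stats::rlnorm(nd, log(mx$debris_ssc_mean),
                                    mx$debris_ssc_sd_log)
    gfp[is_debris] <- auto * stats::rlnorm(nd, 0, 0.3)
    mch[is_debris] <- stats::rlnorm(nd, log(20), 0.5)
    bfp[is_debris] <- stats::rlnorm(nd, log(mx$bfp_uninfected_mean),
                                    mx$bfp_sd_log)
  }
  is_doublet <- cls == "doublet"
  if (any(is_doublet)) {
    nd <- sum(is_doublet)
    gfp[is_doublet] <- 2 * gfp[is_doublet]
    mch[is_doublet] <- 2 * mch[is_doublet]
    bfp[is_doublet] <- 2 * bfp[is_doublet]
    fsc[is_doublet] <- 1.9 * fsc[is_doublet]
    ssc[is_doublet] <- 1.9 * ssc[is_doublet]
    ratio[is_doublet] <- stats::rnorm(nd, mx$doublet_ratio_mean,
                                      mx$doublet_ratio_sd)
  }
  fsc_h <- pmax(fsc * ratio, 0)

  data.frame(FSC_A = fsc, FSC_H = fsc_h, SSC_A = ssc, BFP = bfp,
             GFP = pmax(gfp, 0), mCherry = pmax(mch, 0),
             well = rep(as.character(well), n_cells),
             sgRNA = assignments, class = cls, stringsAsFactors = FALSE)
}

#' Simulate a tail-sorted, sequenced CRISPRi screen
#'
#' Per replicate: sgRNAs are assigned to an `infected_fraction` of cells
#' (uniform library representation by default, optional lognormal skew), the
#' population is simulated, viability and singlet gates are applied followed
#' by the BFP gate, BFP+ events are ranked by their GFP/mCherry ratio, the
#' top and bottom `tail_fraction` are labelled (exactly
#' `floor(N * tail_fraction)` events each), and `reads_per_sample` sequencing
#' reads are drawn multinomially from the sgRNA composition of each tail.
#' Replicates are independent cell cohorts with derived RNG streams.
#'
#' @param library an `sgrna_library`.
#' @param effects an [effect_map()]; `NULL` for an all-null screen.
#' @param calibration a [reporter_calibration()].
#' @param design a [screen_design()].
#' @param codon reporter start codon.
#' @param mixture a [population_mixture()] for the cell cohorts.
#' @return a `screen_counts` data.frame with columns `sgRNA_id`, `gene` and
#'   `rep<k>_high` / `rep<k>_low` read counts, with the ground-truth effects
#'   in `attr(, "truth")` and per-replicate gate/tail diagnostics in
#'   `attr(, "diagnostics")`.
#' @export
simulate_screen <- function(library, effects = NULL,
                            calibration = default_calibration(),
                            design = screen_design(), codon = "CUG",
                            mixture = population_mixture()) {
  library <- as_sgrna_library(library)
  if (is.null(effects)) effects <- effect_map(library)
  n_sg <- nrow(library)
  n_cells <- design$cells_per_replicate
  if (is.null(n_cells))
    n_cells <- ceiling(design$coverage * n_sg / design$infected_fraction)
  reads <- design$reads_per_sample
  if (is.null(reads)) reads <- ceiling(design$coverage * n_sg)

  counts <- data.frame(sgRNA_id = library$sgRNA_id, gene = library$gene,
                       stringsAsFactors = FALSE)
  diagnostics <- list()

  for (r in seq_len(design$replicates)) {
    seed_r <- derive_seed(design$seed, "screen", r)
    set.seed(seed_r)
    infected <- stats::runif(n_cells) < design$infected_fraction
    abundance <- if (design$abundance_sd_log > 0)
      stats::rlnorm(n_sg, 0, design$abundance_sd_log) else rep(1, n_sg)
    assignments <- rep(NA_character_, n_cells)
    assignments[infected] <- sample(library$sgRNA_id, sum(infected),
                                    replace = TRUE, prob = abundance)

    ev <- simulate_population(calibration, n_cells, codon = codon,
                              effects = effects, assignments = assignments,
                              seed = derive_seed(design$seed, "population", r),
                              mixture = mixture)
    g <- gate_events(ev, gate_config())
    bfp_thr <- sqrt(mixture$bfp_infected_mean * mixture$bfp_uninfected_mean)
    pos <- g$events[g$events$BFP > bfp_thr, , drop = FALSE]
    n_gated <- nrow(pos)
    if (n_gated < 1 / design$tail_fraction)
      stop(sprintf("tails undersampled: %d gated BFP+ events for tail fraction %.3g",
                   n_gated, design$tail_fraction))

    ratio <- pos$GFP / pos$mCherry
    ord <- order(ratio)
    n_tail <- floor(n_gated * design$tail_fraction)
    low_idx  <- ord[seq_len(n_tail)]
    high_idx <- ord[seq.int(n_gated - n_tail + 1, n_gated)]
    if (design$sort_retention < 1) {
      keep <- function(ix) ix[stats::runif(length(ix)) < design$sort_retention]
      low_idx <- keep(low_idx); high_idx <- keep(high_idx)
    }

    set.seed(derive_seed(design$seed, "reads", r))
    tail_reads <- function(ix) {
      comp <- table(factor(pos$sgRNA[ix], levels = library$sgRNA_id))
      if (sum(comp) == 0) stop("no sgRNA-carrying cells in sorted tail")
      as.integer(stats::rmultinom(1, reads, prob = comp))
    }
    counts[[sprintf("rep%d_high", r)]] <- tail_reads(high_idx)
    counts[[sprintf("rep%d_low", r)]]  <- tail_reads(low_idx)

    qs <- stats::quantile(ratio, c(design$tail_fraction,
                                   1 - design$tail_fraction), names = FALSE)
    diagnostics[[r]] <- list(
      gate_report = g$report, n_bfp_pos = n_gated, tail_size = n_tail,
      ratio_boundaries = qs,
      boundary_separation_pct = 100 * (qs[2] - qs[1]) / qs[1])
  }

  class(counts) <- c("screen_counts", "data.frame")
  attr(counts, "truth") <- effects
  attr(counts, "design") <- design
  attr(counts, "diagnostics") <- diagnostics
  counts
}

#' Simulate a perturbation-by-gene z-score profile matrix
#'
#' Generates the normalised z-score matrix a single-cell perturbation screen
#' produces after pseudobulking: standard-normal noise plus block signal for
#' each planted cluster (a set of member perturbations sharing an additive
#' effect on a signature gene block).
#'
#' @param n_perturbations,n_genes matrix dimensions (rows, columns).
#' @param cluster_spec list of `list(perturbations =, genes =, effect =)`
#'   with integer index vectors; perturbation memberships must not overlap
#'   across clusters.
#' @param noise_sd SD of the background noise (default 1).
#' @param seed RNG seed.
#' @return a numeric matrix with `attr(, "row_clusters")` giving the planted
#'   row labels (0 = background).
#' @export
simulate_profiles <- function(n_perturbations, n_genes, cluster_spec = list(),
                              noise_sd = 1, seed = 1) {
  stopifnot(n_perturbations >= 1, n_genes >= 1, noise_sd >= 0)
  members <- unlist(lapply(cluster_spec, `[[`, "perturbations"))
  if (anyDuplicated(members))
    stop("overlapping perturbation membership across clusters: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  set.seed(as.integer(seed) %% 2147483647L)
  z <- matrix(stats::rnorm(n_perturbations * n_genes, sd = noise_sd),
              n_perturbations, n_genes,
              dimnames = list(sprintf("pert_%03d", seq_len(n_perturbations)),
                              sprintf("gene_%04d", seq_len(n_genes))))
  labels <- integer(n_perturbations)
  for (k in seq_along(cluster_spec)) {
    cs <- cluster_spec[[k]]
    stopifnot(all(cs$perturbations >= 1), all(cs$perturbations <= n_perturbations),
              all(cs$genes >= 1), all(cs$genes <= n_genes))
    z[cs$perturbations, cs$genes] <- z[cs$perturbations, cs$genes] + cs$effect
    labels[cs$perturbations] <- k
  }
  attr(z, "row_clusters") <- labels
  z
}
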
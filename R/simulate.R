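#' Parameters for the synthetic field-experiment generator
#'
#' Defaults emulate the field design the pipeline targets: five cacao farms,
#' 16 plots, 14-20 rhizosphere samples per plot, a natural soil-Cd gradient
#' spanning 0-4.3 mg kg^-1 with farm-level clustering, per-sample sequencing
#' depths between 2788 and 25083 reads, and a planted responder structure of
#' 13% positively and 15% negatively Cd-responsive taxa.
#'
#' @param n_farms number of farms.
#' @param plots_per_farm integer vector (recycled) of plots per farm;
#'   defaults to 16 plots over five farms.
#' @param samples_per_plot integer range from which the per-plot sample
#'   count is drawn.
#' @param n_taxa number of taxa (>= 10).
#' @param frac_positive_responders,frac_negative_responders fractions of
#'   taxa whose abundance increases/decreases with the soil-Cd category.
#' @param responder_lfc natural-log fold change per Cd-category ordinal step
#'   (low = 0, medium = 1, high = 2).
#' @param farm_effect_sd log-scale sd of per-taxon farm effects.
#' @param depth_range sequencing-depth range (reads per sample).
#' @param overdispersion log-normal sd of per-sample taxon abundance noise.
#' @param cd_range soil-Cd range, mg kg^-1.
#' @param cd_within_sd within-farm sd of soil Cd around the farm mean.
#' @param base_abund_sd sd of baseline taxon log-abundances.
#' @param seed integer seed.
#' @return A validated list of class `"community_sim_params"`.
#' @export
community_sim_params <- function(n_farms = 5,
                                 plots_per_farm = c(3, 3, 3, 3, 4),
                                 samples_per_plot = c(14, 20),
                                 n_taxa = 300,
                                 frac_positive_responders = 0.13,
                                 frac_negative_responders = 0.15,
                                 responder_lfc = 1.0,
                                 farm_effect_sd = 0.25,
                                 depth_range = c(2788, 25083),
                                 overdispersion = 0.4,
                                 cd_range = c(0, 4.3),
                                 cd_within_sd = 0.9,
                                 base_abund_sd = 1.2,
                                 seed = 1L) {
  p <- list(n_farms = n_farms,
            plots_per_farm = rep_len(plots_per_farm, n_farms),
            samples_per_plot = samples_per_plot, n_taxa = n_taxa,
            frac_positive_responders = frac_positive_responders,
            frac_negative_responders = frac_negative_responders,
            responder_lfc = responder_lfc, farm_effect_sd = farm_effect_sd,
            depth_range = as.integer(depth_range),
            overdispersion = overdispersion, cd_range = cd_range,
            cd_within_sd = cd_within_sd, base_abund_sd = base_abund_sd,
            seed = as.integer(seed))
  stopifnot(
    "responder fractions must sum to <= 1" =
      p$frac_positive_responders + p$frac_negative_responders <= 1,
    "responder fractions must be >= 0" =
      p$frac_positive_responders >= 0 && p$frac_negative_responders >= 0,
    "depth_range must be positive with low <= high" =
      all(p$depth_range > 0) && p$depth_range[1] <= p$depth_range[2],
    "n_taxa must be >= 10" = p$n_taxa >= 10,
    "cd_range must be increasing" = p$cd_range[1] < p$cd_range[2]
  )
  class(p) <- "community_sim_params"
  p
}

#' Simulate the field experiment: counts, metadata, ground truth
#'
#' Soil Cd per sample is drawn with farm-level clustering (farm means evenly
#' spread over `cd_range`, within-farm normal jitter, clamped to the range).
#' Taxon log-abundances are baseline + per-farm effect + responder effect
#' (`sign * responder_lfc * Cd-category ordinal`), perturbed by log-normal
#' overdispersion; counts are a multinomial draw at a depth uniform in
#' `depth_range`, so per-sample sampling fractions genuinely vary and the
#' bias-corrected differential-abundance stage has something real to
#' correct.
#'
#' @param params a [community_sim_params()].
#' @return List with `table` ([count_table()]), `metadata` (data frame),
#'   and `truth` (list: `responder_sign` named per-taxon vector in
#'   \{-1, 0, +1\}, `n_positive`, `n_negative`, per-sample `cd_soil`,
#'   `category`, `depth`, `log_sampling_fraction`).
#' @export
#' @examples
#' sim <- simulate_field_experiment(community_sim_params(n_taxa = 50, seed = 3))
#' table(sim$truth$responder_sign)
simulate_field_experiment <- function(params = community_sim_params()) {
  stopifnot(inherits(params, "community_sim_params"))
  set.seed(params$seed)
  cfg_bounds <- pipeline_config()$cd_category_bounds

  # design: farms -> plots -> samples
  farm_of_plot <- rep(seq_len(params$n_farms), params$plots_per_farm)
  n_plots <- length(farm_of_plot)
  n_per_plot <- sample(params$samples_per_plot[1]:params$samples_per_plot[2],
                       n_plots, replace = TRUE)
  farm <- rep(farm_of_plot, n_per_plot)
  plot_id <- rep(seq_len(n_plots), n_per_plot)
  n_samples <- length(farm)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  # soil Cd: farm-clustered gradient over cd_range
  span <- diff(params$cd_range)
  farm_mean <- seq(params$cd_range[1] + 0.1 * span,
                   params$cd_range[2] - 0.1 * span,
                   length.out = params$n_farms)
  cd <- pmin(pmax(farm_mean[farm] + stats::rnorm(n_samples, 0,
                                                 params$cd_within_sd),
                  params$cd_range[1]), params$cd_range[2])
  ord <- findInterval(cd, cfg_bounds) # 0 = low, 1 = medium, 2 = high

  # planted responders
  n_pos <- round(params$frac_positive_responders * params$n_taxa)
  n_neg <- round(params$frac_negative_responders * params$n_taxa)
  sign_vec <- rep(0L, params$n_taxa)
  picks <- sample.int(params$n_taxa, n_pos + n_neg)
  sign_vec[picks[seq_len(n_pos)]] <- 1L
  if (n_neg > 0) sign_vec[picks[n_pos + seq_len(n_neg)]] <- -1L
  taxon_ids <- sprintf("ASV%04d", seq_len(params$n_taxa))
  names(sign_vec) <- taxon_ids

  base <- stats::rnorm(params$n_taxa, 0, params$base_abund_sd)
  farm_eff <- matrix(stats::rnorm(params$n_taxa * params$n_farms, 0,
                                  params$farm_effect_sd),
                     params$n_taxa, params$n_farms)

  depth <- sample(params$depth_range[1]:params$depth_range[2], n_samples,
                  replace = TRUE)
  counts <- matrix(0L, params$n_taxa, n_samples)
  for (j in seq_len(n_samples)) {
    eta <- base + farm_eff[, farm[j]] +
      sign_vec * params$responder_lfc * ord[j] +
      stats::rnorm(params$n_taxa, 0, params$overdispersion)
    p <- exp(eta - max(eta))
    counts[, j] <- stats::rmultinom(1, depth[j], p / sum(p))
  }

  lineage <- sprintf("d__Bacteria;p__Phylum%02d;g__Genus%03d",
                     (seq_len(params$n_taxa) - 1) %% 40 + 1,
                     seq_len(params$n_taxa))
  ct <- count_table(counts, taxon_ids, sample_ids, lineage)
  meta <- data.frame(
    sample_id = sample_ids,
    farm = paste0("farm", farm),
    plot = sprintf("plot%02d", plot_id),
    cd_soil = cd,
    treatment = "control",
    timepoint = NA_character_,
    depth_target = depth,
    stringsAsFactors = FALSE
  )
  truth <- list(
    responder_sign = sign_vec, n_positive = n_pos, n_negative = n_neg,
    cd_soil = stats::setNames(cd, sample_ids),
    category = stats::setNames(c("low", "medium", "high")[ord + 1],
                               sample_ids),
    depth = stats::setNames(depth, sample_ids),
    log_sampling_fraction = stats::setNames(log(depth) - mean(log(depth)),
                                            sample_ids)
  )
  list(table = ct, metadata = meta, truth = truth)
}

#' Simulate a plain two-group count table with planted effects
#'
#' Minimal generator for calibration studies of the differential-abundance
#' model: baseline taxon log-abundances, log-normal overdispersion, and a
#' multinomial draw per sample at a depth uniform in `depth_range`. Taxa
#' named in `planted_lfc` have that natural-log fold change added in the
#' second group.
#'
#' @param n_taxa number of taxa.
#' @param n_per_group samples in each of the two groups.
#' @param planted_lfc named numeric vector (taxon id -> lfc in group 2);
#'   empty for a global null.
#' @param overdispersion log-normal sd of per-sample abundance noise.
#' @param base_abund_sd sd of baseline log-abundances.
#' @param depth_range sequencing-depth range.
#' @param seed integer seed.
#' @return List: `table` ([count_table()]), `metadata` (with a `group`
#'   column, levels `g1`/`g2`), `truth` (the planted vector).
#' @export
simulate_group_counts <- function(n_taxa = 200, n_per_group = c(20, 20),
                                  planted_lfc = numeric(),
                                  overdispersion = 0.4, base_abund_sd = 1.2,
                                  depth_range = c(2788, 25083), seed = 1L) {
  set.seed(seed)
  taxon_ids <- sprintf("ASV%04d", seq_len(n_taxa))
  if (length(planted_lfc) > 0 && !all(names(planted_lfc) %in% taxon_ids)) {
    stop("planted_lfc names must be taxon ids (ASV0001 ...)")
  }
  base <- stats::rnorm(n_taxa, 0, base_abund_sd)
  names(base) <- taxon_ids
  n_samples <- sum(n_per_group)
  group <- rep(c("g1", "g2"), n_per_group)
  depth <- sample(depth_range[1]:depth_range[2], n_samples, replace = TRUE)
  counts <- matrix(0L, n_taxa, n_samples)
  for (j in seq_len(n_samples)) {
    eta <- base + stats::rnorm(n_taxa, 0, overdispersion)
    if (group[j] == "g2" && length(planted_lfc) > 0) {
      eta[names(planted_lfc)] <- eta[names(planted_lfc)] + planted_lfc
    }
    p <- exp(eta - max(eta))
    counts[, j] <- stats::rmultinom(1, depth[j], p / sum(p))
  }
  ids <- sprintf("%s_%02d", group, stats::ave(seq_len(n_samples), group,
                                              FUN = seq_along))
  ct <- count_table(counts, taxon_ids, ids)
  meta <- data.frame(sample_id = ids, farm = "farm1", plot = "plot01",
                     cd_soil = 0, treatment = "control",
                     timepoint = NA_character_, group = group,
                     stringsAsFactors = FALSE)
  list(table = ct, metadata = meta, truth = planted_lfc)
}

#' Parameters for the paired-thermogram generator
#'
#' @param q_max true asymptotic heat, J.
#' @param mu_max true maximal heat-production rate, J h^-1.
#' @param lag true adaptation phase, h.
#' @param spike_lag_extension extra lag (h) in the spiked member; Cd-spiked
#'   soils show a longer adaptation phase than their controls.
#' @param spike_qmax_multiplier factor applied to `q_max` in the spiked
#'   member.
#' @param noise_sd additive Gaussian noise on heat flow, mW.
#' @param drift_slope linear baseline drift, mW h^-1.
#' @param duration assay length, h.
#' @param sampling_interval h between readings.
#' @param sample_id identifier shared by the pair.
#' @param seed optional integer seed (noise only).
#' @return A validated list of class `"thermo_sim_params"`.
#' @export
thermo_sim_params <- function(q_max = 2, mu_max = 0.1, lag = 10,
                              spike_lag_extension = 5,
                              spike_qmax_multiplier = 1.3,
                              noise_sd = 0.01, drift_slope = 0,
                              duration = 80, sampling_interval = 0.5,
                              sample_id = "sim", seed = NULL) {
  p <- list(q_max = q_max, mu_max = mu_max, lag = lag,
            spike_lag_extension = spike_lag_extension,
            spike_qmax_multiplier = spike_qmax_multiplier,
            noise_sd = noise_sd, drift_slope = drift_slope,
            duration = duration, sampling_interval = sampling_interval,
            sample_id = sample_id, seed = seed)
  stopifnot(
    "q_max must be > 0" = p$q_max > 0,
    "mu_max must be > 0" = p$mu_max > 0,
    "lag must be >= 0" = p$lag >= 0,
    "duration must exceed lag" = p$duration > p$lag,
    "sampling_interval must be > 0" = p$sampling_interval > 0
  )
  class(p) <- "thermo_sim_params"
  p
}

#' Simulate a paired control/Cd-spiked thermogram
#'
#' Noiseless flow is the exact time derivative of the Gompertz
#' cumulative-heat model ([gompertz_flow()]). The spiked member uses
#' `lag + spike_lag_extension` and `q_max * spike_qmax_multiplier`;
#' additive Gaussian noise and linear drift are applied on top. Both
#' members share one time grid.
#'
#' @param params a [thermo_sim_params()].
#' @return List with `control`, `spiked` ([thermogram()]s) and `truth`
#'   (true parameters per member).
#' @export
simulate_thermogram_pair <- function(params = thermo_sim_params()) {
  stopifnot(inherits(params, "thermo_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  t <- seq(0, params$duration, by = params$sampling_interval)
  spiked_qmax <- params$q_max * params$spike_qmax_multiplier
  spiked_lag <- params$lag + params$spike_lag_extension
  f_ctrl <- gompertz_flow(t, params$q_max, params$mu_max, params$lag)
  f_spk <- gompertz_flow(t, spiked_qmax, params$mu_max, spiked_lag)
  noisify <- function(f) {
    f + params$drift_slope * t +
      if (params$noise_sd > 0) stats::rnorm(length(t), 0, params$noise_sd)
      else 0
  }
  list(
    control = thermogram(t, noisify(f_ctrl), params$sample_id, "control"),
    spiked = thermogram(t, noisify(f_spk), params$sample_id, "spiked"),
    truth = list(
      control = c(q_max = params$q_max, mu_max = params$mu_max,
                  lag = params$lag),
      spiked = c(q_max = spiked_qmax, mu_max = params$mu_max,
                 lag = spiked_lag)
    )
  )
}

#' Simulate counts over the calorimetry timepoints S, P, E
#'
#' Generates per-arm (control/spiked) count tables at the start, peak and
#' end of the assay. Taxa in `enriched_taxa` change log-linearly S -> P -> E
#' in the spiked arm only, reaching `sign * lfc` at E; taxa in
#' `non_response_taxa` change identically in both arms (growth on the
#' medium, not on Cd); all other taxa are stable.
#'
#' @param params a [community_sim_params()] (taxa, depths, overdispersion
#'   and `responder_lfc` are reused; the field design fields are not).
#' @param enriched_taxa named numeric vector of +1/-1 signs, names being
#'   taxon ids (or indices into `1:n_taxa`).
#' @param non_response_taxa character vector of taxon ids enriched in both
#'   arms; must be disjoint from `enriched_taxa`.
#' @param n_replicates samples per arm x timepoint.
#' @return List with `table`, `metadata`, `truth`.
#' @export
simulate_timepoint_counts <- function(params = community_sim_params(),
                                      enriched_taxa = numeric(),
                                      non_response_taxa = character(),
                                      n_replicates = 10) {
  stopifnot(inherits(params, "community_sim_params"))
  set.seed(params$seed)
  taxon_ids <- sprintf("ASV%04d", seq_len(params$n_taxa))
  if (length(enriched_taxa) > 0 && is.null(names(enriched_taxa))) {
    stop("enriched_taxa must be a named sign vector")
  }
  if (!all(names(enriched_taxa) %in% taxon_ids)) {
    stop("enriched_taxa names must be taxon ids")
  }
  if (!all(non_response_taxa %in% taxon_ids)) {
    stop("non_response_taxa must be taxon ids")
  }
  if (length(intersect(names(enriched_taxa), non_response_taxa)) > 0) {
    stop("enriched and non-response sets must be disjoint")
  }
  if (length(enriched_taxa) > 0 && !all(enriched_taxa %in% c(-1, 1))) {
    stop("enrichment signs must be +1 or -1")
  }

  base <- stats::rnorm(params$n_taxa, 0, params$base_abund_sd)
  names(base) <- taxon_ids
  steps <- c(S = 0, P = 0.5, E = 1)
  arms <- c("control", "spiked")
  lfc <- params$responder_lfc

  cols <- list(); ids <- character(); meta <- list()
  for (arm in arms) {
    for (tp in names(steps)) {
      for (r in seq_len(n_replicates)) {
        eta <- base
        if (length(enriched_taxa) > 0 && arm == "spiked") {
          eta[names(enriched_taxa)] <- eta[names(enriched_taxa)] +
            enriched_taxa * lfc * steps[tp]
        }
        if (length(non_response_taxa) > 0) {
          eta[non_response_taxa] <- eta[non_response_taxa] + lfc * steps[tp]
        }
        eta <- eta + stats::rnorm(params$n_taxa, 0, params$overdispersion)
        depth <- sample(params$depth_range[1]:params$depth_range[2], 1)
        p <- exp(eta - max(eta))
        cols[[length(cols) + 1]] <- stats::rmultinom(1, depth, p / sum(p))
        id <- sprintf("%s_%s_%02d", substr(arm, 1, 3), tp, r)
        ids <- c(ids, id)
        meta[[length(meta) + 1]] <- data.frame(
          sample_id = id, farm = "farm1", plot = "plot01", cd_soil = 0,
          treatment = arm, timepoint = tp, stringsAsFactors = FALSE
        )
      }
    }
  }
  counts <- do.call(cbind, cols)
  ct <- count_table(counts, taxon_ids, ids)
  truth <- list(
    enriched = enriched_taxa,
    non_response = non_response_taxa,
    base_log_abundance = base
  )
  list(table = ct, metadata = do.call(rbind, meta), truth = truth)
}
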
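#' Pipeline configuration
#'
#' Builds the configuration object shared by every pipeline stage. All
#' defaults can be overridden by name; [read_config()] layers a YAML file on
#' top of these defaults and CLI flags override both.
#'
#' @param random_seed integer seed used by every randomized stage.
#' @param alpha significance level for all hypothesis tests (in (0,1)).
#' @param n_permutations number of permutations for PERMANOVA.
#' @param pseudo_count value added to counts before taking logs in the
#'   differential-abundance model.
#' @param cd_category_bounds increasing numeric pair (mg kg^-1) splitting soil
#'   Cd into low `[0, b1)`, medium `[b1, b2)` and high `[b2, Inf)`.
#' @param spike_dose CdCl2 spiking dose, mg L^-1.
#' @param assay_hours duration of the calorimetry assay, hours.
#' @param fallback_peak_hour sampling hour used when no activity peak is
#'   detected.
#' @param prevalence_threshold fraction of a group's samples in which a taxon
#'   must pass detection to count as occurring (core-taxa analysis).
#' @param detection_threshold relative-abundance detection limit for the
#'   core-taxa analysis.
#' @param peak_smooth_window moving-average window (hours) used before peak
#'   detection.
#' @param peak_prominence minimum rise of the smoothed flow (mW) above its
#'   minimum for a maximum to qualify as a peak.
#' @param rarefy logical; subsample every sample to the minimum depth before
#'   diversity analysis. Off by default.
#' @param bray_on_proportions logical; compute Bray-Curtis on relative
#'   abundances (default) rather than raw counts.
#' @param enrichment_rule `"union"` (enriched at P or E vs S) or
#'   `"intersection"`.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(alpha = 0.01)
#' cfg$alpha
pipeline_config <- function(random_seed = 1L,
                            alpha = 0.05,
                            n_permutations = 999L,
                            pseudo_count = 0.5,
                            cd_category_bounds = c(1, 2),
                            spike_dose = 1,
                            assay_hours = 80,
                            fallback_peak_hour = 37,
                            prevalence_threshold = 0.001,
                            detection_threshold = 1 / 100,
                            peak_smooth_window = 2,
                            peak_prominence = 0.1,
                            rarefy = FALSE,
                            bray_on_proportions = TRUE,
                            enrichment_rule = c("union", "intersection")) {
  enrichment_rule <- match.arg(enrichment_rule)
  cfg <- list(
    random_seed = as.integer(random_seed),
    alpha = alpha,
    n_permutations = as.integer(n_permutations),
    pseudo_count = pseudo_count,
    cd_category_bounds = as.numeric(cd_category_bounds),
    spike_dose = spike_dose,
    assay_hours = assay_hours,
    fallback_peak_hour = fallback_peak_hour,
    prevalence_threshold = prevalence_threshold,
    detection_threshold = detection_threshold,
    peak_smooth_window = peak_smooth_window,
    peak_prominence = peak_prominence,
    rarefy = isTRUE(rarefy),
    bray_on_proportions = isTRUE(bray_on_proportions),
    enrichment_rule = enrichment_rule
  )
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    "alpha must lie in (0,1)" = is.numeric(cfg$alpha) &&
      cfg$alpha > 0 && cfg$alpha < 1,
    "cd_category_bounds must be two strictly increasing values" =
      length(cfg$cd_category_bounds) == 2 &&
        cfg$cd_category_bounds[1] < cfg$cd_category_bounds[2] &&
        all(cfg$cd_category_bounds > 0),
    "n_permutations must be positive" = cfg$n_permutations >= 1,
    "pseudo_count must be > 0" = cfg$pseudo_count > 0,
    "prevalence_threshold must be > 0" = cfg$prevalence_threshold > 0,
    "detection_threshold must be > 0" = cfg$detection_threshold > 0,
    "assay_hours must be > 0" = cfg$assay_hours > 0
  )
  invisible(cfg)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML key/value file and merges it over [pipeline_config()]
#' defaults. Unknown keys are rejected so typos do not silently fall back to
#' defaults.
#'
#' @param path path to a YAML configuration file.
#' @return A `pipeline_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("cdresp pipeline configuration (hash ", config_hash(x), ")\n", sep = "")
  for (k in names(x)) {
    cat(sprintf("  %-22s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}

#' Short content hash of a configuration
#'
#' 32-bit FNV-1a hash of the deparsed configuration, used in provenance
#' headers so outputs record the exact settings that produced them.
#'
#' @param cfg a `pipeline_config`.
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

provenance_line <- function(cfg, seed = cfg$random_seed) {
  sprintf("# provenance: config=%s seed=%d", config_hash(cfg), as.integer(seed))
}
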
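#' Assign soil-Cd categories
#'
#' Maps soil Cd (mg kg^-1) to `low`, `medium` or `high` using half-open
#' intervals closed on the left — low `[0, b1)`, medium `[b1, b2)`, high
#' `[b2, Inf)` — so every non-negative concentration belongs to exactly one
#' category.
#'
#' @param cd_soil numeric vector of soil Cd concentrations, mg kg^-1.
#' @param config a [pipeline_config()] (uses `cd_category_bounds`).
#' @return Character vector in \{low, medium, high\}.
#' @export
#' @examples
#' assign_cd_category(c(0.5, 1.0, 3.0)) # low, medium, high
assign_cd_category <- function(cd_soil, config = pipeline_config()) {
  if (any(!is.finite(cd_soil)) || any(cd_soil < 0)) {
    stop("cd_soil must be finite and >= 0")
  }
  c("low", "medium", "high")[findInterval(cd_soil,
                                          config$cd_category_bounds) + 1]
}

#' Summarize responsive-taxon calls
#'
#' @param calls data frame of responsive calls with a `direction` column
#'   (`positive`/`negative`) and `taxon_id` within `universe`.
#' @param universe character vector of all taxa under consideration.
#' @param rank label recorded in the summary (e.g. "phylum", "asv").
#' @return List of class `"response_summary"`: `n_taxa_total`,
#'   `n_responsive`, `fraction_responsive`, `fraction_positive`,
#'   `fraction_negative`, `fraction_stable`, `rank`.
#' @export
#' @examples
#' calls <- data.frame(taxon_id = paste0("t", 1:27),
#'                     direction = rep(c("positive", "negative"), c(16, 11)))
#' summarize_response(calls, paste0("t", 1:100))$fraction_responsive # 0.27
summarize_response <- function(calls, universe, rank = "asv") {
  if (length(universe) == 0) stop("empty taxon universe")
  if (!all(calls$taxon_id %in% universe)) {
    stop("calls contain taxa outside the universe")
  }
  n <- length(universe)
  n_pos <- sum(calls$direction == "positive")
  n_neg <- sum(calls$direction == "negative")
  out <- list(
    n_taxa_total = n,
    n_responsive = n_pos + n_neg,
    fraction_responsive = (n_pos + n_neg) / n,
    fraction_positive = n_pos / n,
    fraction_negative = n_neg / n,
    fraction_stable = 1 - (n_pos + n_neg) / n,
    rank = rank
  )
  class(out) <- "response_summary"
  out
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf(
    "response summary (%s level): %d/%d responsive (%.1f%%: %.1f%% up, %.1f%% down), %.1f%% stable\n",
    x$rank, x$n_responsive, x$n_taxa_total, 100 * x$fraction_responsive,
    100 * x$fraction_positive, 100 * x$fraction_negative,
    100 * x$fraction_stable
  ))
  invisible(x)
}

#' Composition-based Cd-responsive classification
#'
#' Classifies taxa from a differential-abundance result computed with the
#' low soil-Cd category as reference: a taxon is responsive when
#' `q <= alpha`, with direction from the sign of its log fold change.
#'
#' @param da result of [differential_abundance()].
#' @param alpha significance level.
#' @param contrast_label recorded on each call (e.g. "high-vs-low").
#' @param rank label for the summary.
#' @return List: `calls` (data frame: `taxon_id`, `evidence` =
#'   "composition", `direction`, `contrast`) and `summary`
#'   ([summarize_response()] over the tested taxa).
#' @export
classify_composition_responders <- function(da, alpha = 0.05,
                                            contrast_label = "high-vs-low",
                                            rank = "asv") {
  if (nrow(da) == 0) stop("empty differential-abundance result")
  tested <- !da$structural_zero & !is.na(da$q)
  hit <- tested & da$q <= alpha
  calls <- data.frame(
    taxon_id = da$taxon_id[hit],
    evidence = "composition",
    direction = ifelse(da$lfc[hit] > 0, "positive", "negative"),
    contrast = contrast_label,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(calls = calls,
       summary = summarize_response(calls, da$taxon_id[tested], rank))
}

#' Activity-based Cd-responsive classification (spiked minus control)
#'
#' A taxon is Cd-responsive on activity evidence when it is enriched in
#' the Cd-spiked arm but not in the matching control arm; taxa enriched in
#' both arms grew on the medium, not on Cd, and are labelled non-response.
#'
#' @param enriched_spiked named numeric vector of signs (+1/-1) over taxa
#'   enriched in the spiked arm (or a character vector, treated as all +1).
#' @param enriched_control character vector (or named vector) of taxa
#'   enriched in the control arm.
#' @return Data frame of calls: `taxon_id`, `evidence` = "activity",
#'   `direction`, `contrast` = "spiked-not-control".
#' @export
#' @examples
#' classify_activity_responders(c(A = 1, B = 1), c("B"))$taxon_id # "A"
classify_activity_responders <- function(enriched_spiked, enriched_control) {
  if (is.character(enriched_spiked)) {
    enriched_spiked <- stats::setNames(rep(1, length(enriched_spiked)),
                                       enriched_spiked)
  }
  ctrl <- if (is.character(enriched_control)) enriched_control
          else names(enriched_control)
  keep <- setdiff(names(enriched_spiked), ctrl)
  data.frame(
    taxon_id = keep,
    evidence = rep("activity", length(keep)),
    direction = ifelse(enriched_spiked[keep] > 0, "positive", "negative"),
    contrast = rep("spiked-not-control", length(keep)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-arm enrichment across the assay timepoints
#'
#' Runs the differential-abundance model within each arm (control, spiked)
#' with the start timepoint S as reference against the peak P and the end
#' E. A taxon is enriched in an arm when significantly increased (positive
#' log fold change at `q <= alpha`) in either contrast (`"union"`, the
#' default) or in both (`"intersection"`).
#'
#' @param ct a [count_table()] over the S/P/E x control/spiked samples.
#' @param metadata metadata with `treatment` and `timepoint` columns.
#' @param config a [pipeline_config()] (`alpha`, `pseudo_count`,
#'   `enrichment_rule`).
#' @return List with one named sign vector per arm (`control`, `spiked`):
#'   +1/-1 over taxa significantly changed under the chosen rule, with
#'   enrichment meaning positive sign. Attribute `"changed"` carries the
#'   full significantly-changed sets including negatives.
#' @export
timepoint_enrichment <- function(ct, metadata, config = pipeline_config()) {
  meta <- match_metadata(ct, metadata)
  out <- list()
  changed <- list()
  for (arm in c("control", "spiked")) {
    in_arm <- meta$treatment == arm
    tps <- unique(meta$timepoint[in_arm])
    if (!"S" %in% tps) stop("arm '", arm, "' has no timepoint S samples")
    later <- intersect(c("P", "E"), tps)
    if (length(later) == 0) {
      stop("arm '", arm, "' has no timepoint P or E samples")
    }
    sub <- count_table(ct$counts[, in_arm, drop = FALSE], ct$taxon_ids,
                       ct$samples[in_arm], ct$lineage)
    sig_sets <- lapply(later, function(tp) {
      da <- differential_abundance(
        sub, meta[in_arm, , drop = FALSE],
        da_contrast("timepoint", "S", tp), config
      )
      hit <- !da$structural_zero & !is.na(da$q) & da$q <= config$alpha
      stats::setNames(sign(da$lfc[hit]), da$taxon_id[hit])
    })
    pos_sets <- lapply(sig_sets, function(s) names(s)[s > 0])
    enriched_ids <- if (config$enrichment_rule == "union") {
      Reduce(union, pos_sets)
    } else {
      Reduce(intersect, pos_sets)
    }
    all_changed <- unlist(sig_sets)
    all_changed <- all_changed[!duplicated(names(all_changed))]
    out[[arm]] <- stats::setNames(rep(1, length(enriched_ids)), enriched_ids)
    changed[[arm]] <- all_changed
  }
  attr(out, "changed") <- changed
  out
}

#' Core-taxa Venn partition across groups
#'
#' A taxon occurs in a group when its relative abundance reaches the
#' detection threshold in at least `prevalence_threshold` of the group's
#' samples. The output partitions occurring taxa into the regions of the
#' Venn diagram over groups (each taxon lands in exactly one region).
#'
#' @param ct a [count_table()] with no all-zero samples.
#' @param grouping group label per sample (e.g. farm or Cd category).
#' @param config a [pipeline_config()] (`detection_threshold`,
#'   `prevalence_threshold`).
#' @return List: `occurrence` (logical taxa x groups matrix), `regions`
#'   (named integer vector, names are `+`-joined group combinations),
#'   `shared_all` (count in the all-groups region), `n_occurring`.
#' @export
core_taxa <- function(ct, grouping, config = pipeline_config()) {
  check_no_empty_samples(ct)
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == ncol(ct$counts))
  lev <- unique(grouping)
  rel <- sweep(ct$counts, 2, colSums(ct$counts), "/")
  occ <- vapply(lev, function(g) {
    idx <- which(grouping == g)
    if (length(idx) == 0) stop("group '", g, "' has no samples")
    det <- rel[, idx, drop = FALSE] >= config$detection_threshold
    rowMeans(det) >= config$prevalence_threshold
  }, logical(nrow(ct$counts)))
  rownames(occ) <- ct$taxon_ids
  occurring <- rowSums(occ) > 0
  region_of <- apply(occ[occurring, , drop = FALSE], 1, function(z) {
    paste(lev[z], collapse = "+")
  })
  regions <- table(region_of)
  all_key <- paste(lev, collapse = "+")
  list(
    occurrence = occ,
    regions = stats::setNames(as.integer(regions), names(regions)),
    shared_all = if (all_key %in% names(regions))
      as.integer(regions[[all_key]]) else 0L,
    n_occurring = sum(occurring)
  )
}
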
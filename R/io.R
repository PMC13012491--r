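#' ASV count table
#'
#' Constructs the validated taxa-by-samples count container used throughout
#' the pipeline. Counts must be non-negative integers; taxon and sample ids
#' must be unique. All-zero sample columns are allowed here (they can occur
#' in raw inputs) but are rejected by every downstream statistic, where a
#' sample with no reads has undefined relative abundance.
#'
#' @param counts integer matrix, taxa in rows, samples in columns. Row and
#'   column names become taxon and sample ids if `taxon_ids`/`samples` are
#'   not supplied.
#' @param taxon_ids character vector of unique ASV identifiers.
#' @param samples character vector of unique sample identifiers.
#' @param lineage optional per-taxon taxonomic path (domain to genus).
#' @return An object of class `"count_table"`: a list with elements
#'   `counts`, `taxon_ids`, `samples`, `lineage`.
#' @export
#' @examples
#' ct <- count_table(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("ASV", 1:3), c("s1", "s2"))))
#' dim(ct$counts)
count_table <- function(counts, taxon_ids = rownames(counts),
                        samples = colnames(counts), lineage = NULL) {
  counts <- as.matrix(counts)
  if (is.null(taxon_ids) || is.null(samples)) {
    stop("taxon and sample identifiers are required")
  }
  storage_ok <- is.numeric(counts) && all(is.finite(counts))
  if (!storage_ok) stop("counts must be finite numbers")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-integer or negative count at taxon '%s', sample '%s'",
      taxon_ids[bad[1, 1]], samples[bad[1, 2]]
    ))
  }
  if (anyDuplicated(taxon_ids)) {
    stop("duplicate taxon id: ", taxon_ids[duplicated(taxon_ids)][1])
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample id: ", samples[duplicated(samples)][1])
  }
  if (!is.null(lineage) && length(lineage) != nrow(counts)) {
    stop("lineage must have one entry per taxon")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(taxon_ids, samples)
  structure(
    list(counts = counts, taxon_ids = taxon_ids, samples = samples,
         lineage = lineage),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf(
    "count_table: %d taxa x %d samples (total reads %s)\n",
    nrow(x$counts), ncol(x$counts), format(sum(x$counts), big.mark = ",")
  ))
  invisible(x)
}

# Shared guard: downstream statistics refuse empty sample columns.
check_no_empty_samples <- function(ct) {
  empty <- colSums(ct$counts) == 0
  if (any(empty)) {
    stop("all-zero sample column(s): ",
         paste(ct$samples[empty], collapse = ", "))
  }
  invisible(ct)
}

#' Read / write an ASV count table (TSV)
#'
#' Tab-separated, taxa as rows: header `taxon_id<TAB>[lineage<TAB>]sample...`.
#' Lines starting with `#` (provenance headers) are skipped on read.
#'
#' @param path file path.
#' @return [read_count_table()] returns a validated [count_table()];
#'   `write_count_table` returns `path` invisibly.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 2) stop("count table needs a taxon id column plus samples")
  if (names(df)[1] != "taxon_id") stop("first column must be 'taxon_id'")
  taxon_ids <- df[[1]]
  has_lineage <- ncol(df) >= 2 && names(df)[2] == "lineage"
  lineage <- if (has_lineage) df[[2]] else NULL
  first_sample <- if (has_lineage) 3L else 2L
  if (ncol(df) < first_sample) stop("no sample columns found")
  samples <- names(df)[first_sample:ncol(df)]
  mat <- sapply(first_sample:ncol(df), function(j) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      stop(sprintf(
        "non-integer or negative count '%s' at row '%s', column '%s'",
        df[[j]][bad[1]], taxon_ids[bad[1]], names(df)[j]
      ))
    }
    v
  })
  mat <- matrix(mat, nrow = length(taxon_ids),
                dimnames = list(taxon_ids, samples))
  count_table(mat, taxon_ids, samples, lineage)
}

#' @rdname read_count_table
#' @param ct a [count_table()].
#' @param config optional `pipeline_config`; when given, a provenance header
#'   line (config hash + seed) is written before the table.
#' @export
write_count_table <- function(ct, path, config = NULL) {
  df <- data.frame(taxon_id = ct$taxon_ids, stringsAsFactors = FALSE)
  if (!is.null(ct$lineage)) df$lineage <- ct$lineage
  df <- cbind(df, as.data.frame(ct$counts, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) writeLines(provenance_line(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata (CSV)
#'
#' Columns: `sample_id, farm, plot, cd_soil, treatment[, timepoint,
#' depth_target]`. `cd_soil` is soil cadmium in mg kg^-1 and must be finite
#' and non-negative; `treatment` is `control` or `spiked`; `timepoint` is
#' `S`, `P` or `E`, or empty for field samples. Missing required fields are
#' errors, not defaults.
#'
#' @param path file path.
#' @return A data frame with validated columns.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param meta metadata data frame.
#' @param config optional `pipeline_config` for a provenance header.
#' @export
write_sample_metadata <- function(meta, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) writeLines(provenance_line(config), con)
  utils::write.csv(meta, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_sample_metadata
#' @param df a candidate metadata data frame.
#' @export
validate_sample_metadata <- function(df) {
  required <- c("sample_id", "farm", "plot", "cd_soil", "treatment")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("metadata missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         df$sample_id[duplicated(df$sample_id)][1])
  }
  df$cd_soil <- as.numeric(df$cd_soil)
  if (any(!is.finite(df$cd_soil)) || any(df$cd_soil < 0)) {
    stop("cd_soil must be finite and >= 0 for every sample")
  }
  if (!all(df$treatment %in% c("control", "spiked"))) {
    stop("treatment must be 'control' or 'spiked'")
  }
  if ("timepoint" %in% names(df)) {
    tp <- df$timepoint
    tp[tp == ""] <- NA
    if (!all(is.na(tp) | tp %in% c("S", "P", "E"))) {
      stop("timepoint must be S, P, E or empty (field sample)")
    }
    df$timepoint <- tp
  } else {
    df$timepoint <- NA_character_
  }
  df
}

# Every sample in the count table must have exactly one metadata row.
match_metadata <- function(ct, meta) {
  idx <- match(ct$samples, meta$sample_id)
  if (anyNA(idx)) {
    stop("no metadata row for sample(s): ",
         paste(ct$samples[is.na(idx)], collapse = ", "))
  }
  meta[idx, , drop = FALSE]
}

#' Thermogram: one ampoule's heat-flow record
#'
#' @param time hours, strictly increasing.
#' @param heat_flow heat flow in mW, same length as `time`. Negative values
#'   (instrument baseline dips) are retained.
#' @param sample_id identifier shared by the control/spiked pair.
#' @param treatment `"control"` or `"spiked"`.
#' @return An object of class `"thermogram"`.
#' @export
thermogram <- function(time, heat_flow, sample_id = "sample",
                       treatment = c("control", "spiked")) {
  treatment <- match.arg(treatment)
  time <- as.numeric(time)
  heat_flow <- as.numeric(heat_flow)
  if (length(time) != length(heat_flow)) {
    stop("time and heat_flow must have the same length")
  }
  if (any(!is.finite(time)) || any(!is.finite(heat_flow))) {
    stop("thermogram values must be finite")
  }
  if (length(time) >= 2 && any(diff(time) <= 0)) {
    stop("time must be strictly increasing")
  }
  structure(
    list(time = time, heat_flow = heat_flow, sample_id = sample_id,
         treatment = treatment),
    class = "thermogram"
  )
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf(
    "thermogram '%s' (%s): %d points over %.1f h, peak flow %.3g mW\n",
    x$sample_id, x$treatment, length(x$time),
    if (length(x$time)) max(x$time) - min(x$time) else 0,
    if (length(x$heat_flow)) max(x$heat_flow) else NA_real_
  ))
  invisible(x)
}

#' Read / write a thermogram CSV
#'
#' Format: comment header lines `# sample_id=...`, `# treatment=control|spiked`,
#' `# time_unit=h|s`, then columns `time,heat_flow_mW`. The time unit must be
#' declared; it is never guessed. Time is normalized to hours on load.
#'
#' @param path file path.
#' @return [read_thermogram()] returns a [thermogram()].
#' @export
read_thermogram <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- regmatches(hdr, regexec(paste0("^#\\s*", key, "\\s*=\\s*(\\S+)"), hdr))
    hit <- Filter(function(x) length(x) == 2, m)
    if (length(hit) == 0) return(NA_character_)
    hit[[1]][2]
  }
  unit <- get_field("time_unit")
  if (is.na(unit) || !unit %in% c("h", "s")) {
    stop("thermogram file must declare '# time_unit=h' or '# time_unit=s'")
  }
  sample_id <- get_field("sample_id")
  if (is.na(sample_id)) sample_id <- basename(path)
  treatment <- get_field("treatment")
  if (is.na(treatment)) treatment <- "control"
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("time", "heat_flow_mW") %in% names(df))) {
    stop("thermogram CSV needs columns 'time' and 'heat_flow_mW'")
  }
  t <- if (unit == "s") df$time / 3600 else df$time
  thermogram(t, df$heat_flow_mW, sample_id, treatment)
}

#' @rdname read_thermogram
#' @param tg a [thermogram()]; written with `time_unit=h`.
#' @export
write_thermogram <- function(tg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# sample_id=", tg$sample_id),
    paste0("# treatment=", tg$treatment),
    "# time_unit=h"
  ), con)
  utils::write.csv(
    data.frame(time = tg$time, heat_flow_mW = tg$heat_flow),
    con, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# Generic provenance-stamped TSV writer used by CLI stages.
write_result_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
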
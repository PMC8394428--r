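# Plain-text I/O: cohort tables, per-acquisition event tables, reports.

#' Read a genotype cohort CSV
#'
#' Expects columns `subject_id`, `group`, `genotype`; empty strings or the
#' literal `missing` in `genotype` become `NA`.
#'
#' @param path CSV file path.
#' @return Cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "group", "genotype") %in% names(raw)))
  raw$genotype[raw$genotype %in% c("", "missing", "NA")] <- NA_character_
  tibble::as_tibble(raw)
}

#' @rdname read_cohort_csv
#' @param cohort Cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a per-acquisition event table
#'
#' Uses the exchange dialect `time_s,fsc,ssc,cd14,cd16,<marker>` where the
#' final column is named after the stained marker (`ccr5` for expression
#' panels, `fluo4` for kinetic runs).
#'
#' @param events Event tibble with a `marker` column and a `marker_name`
#'   attribute (or supply `marker_name`).
#' @param path Output CSV path.
#' @param marker_name Column name for the marker channel.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path,
                             marker_name = attr(events, "marker_name")) {
  marker_name <- marker_name %||% "marker"
  out <- events[, c("time_s", "fsc", "ssc", "cd14", "cd16", "marker")]
  names(out)[names(out) == "marker"] <- marker_name
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-acquisition event table
#'
#' Accepts the dialect written by [write_events_csv()]; whichever of `ccr5`
#' or `fluo4` (or `marker`) is present becomes the internal `marker` column,
#' and acquisition metadata can be attached for downstream scoring.
#'
#' @param path CSV file path.
#' @param stimulus,stim_time_s,subject_id,genotype Optional acquisition
#'   metadata stored as attributes.
#' @return Event tibble.
#' @export
read_events_csv <- function(path, stimulus = NULL, stim_time_s = NULL,
                            subject_id = NULL, genotype = NULL) {
  raw <- tibble::as_tibble(utils::read.csv(path))
  marker_col <- intersect(c("ccr5", "fluo4", "marker"), names(raw))
  if (length(marker_col) != 1L) {
    rlang::abort("Expected exactly one marker column (ccr5, fluo4 or marker).")
  }
  names(raw)[names(raw) == marker_col] <- "marker"
  attr(raw, "marker_name") <- if (marker_col == "marker") NULL else marker_col
  attr(raw, "stimulus") <- stimulus
  attr(raw, "stim_time_s") <- stim_time_s
  attr(raw, "subject_id") <- subject_id
  attr(raw, "genotype") <- genotype
  raw
}

#' Published genotype counts for rs1799987
#'
#' The case-control genotype counts for the CCR5 -2459 A>G promoter
#' polymorphism (106 Löfgren's syndrome patients, 257 healthy controls),
#' shipped as a plain-text fixture.
#'
#' @return Tibble with columns `group`, `n_AA`, `n_AG`, `n_GG`.
#' @export
rs1799987_counts <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "rs1799987_genotype_counts.csv",
                package = "ccr5flux")))
}

#' Published MIP-1alpha responder counts by genotype
#'
#' Counts of patients with / without a calcium-influx response to MIP-1alpha
#' among the 21 functionally studied Löfgren's syndrome patients, by
#' rs1799987 genotype.
#'
#' @return Tibble with columns `genotype`, `responder`, `non_responder`.
#' @export
mip1a_responder_counts <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "mip1a_responder_counts.csv",
                package = "ccr5flux")))
}

#' Expand genotype counts into a subject-level cohort
#'
#' @param counts Tibble with `group`, `n_AA`, `n_AG`, `n_GG` (one row per
#'   group), e.g. [rs1799987_counts()].
#' @return Cohort tibble (`subject_id`, `group`, `genotype`).
#' @export
counts_to_cohort <- function(counts) {
  rows <- purrr::pmap_dfr(counts, function(group, n_AA, n_AG, n_GG, ...) {
    tibble::tibble(group = group,
                   genotype = rep(GENOTYPES, c(n_AA, n_AG, n_GG)))
  })
  dplyr::mutate(rows,
                subject_id = sprintf("%s_%03d", .data$group,
                                     seq_len(dplyr::n())),
                .by = "group", .before = 1)
}

#' Subject-level cohort reconstructed from the published genotype counts
#'
#' @return Cohort tibble with 363 subjects.
#' @export
rs1799987_cohort <- function() {
  counts_to_cohort(rs1799987_counts())
}
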
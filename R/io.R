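#' Read and write pipeline tables
#'
#' Plain-text interchange formats: tab-separated tables for regions,
#' participants, coverage, densities and per-subject time series, and JSON
#' for circuits and planted ground truth.
#'
#' @param file,dir paths
#' @param x,cohort,circuits objects to write
#' @name io
NULL

#' @rdname io
#' @export
readRegionTable <- function(file) {
  regionTable(utils::read.delim(file, stringsAsFactors = FALSE))
}

#' @rdname io
#' @export
readParticipants <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' @rdname io
#' @export
readCoverage <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io
#' @export
readDensity <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  stats::setNames(df$density, df$region_id)
}

#' Read one subject's region-by-volume time series
#'
#' Expects a header row of volume indices and region ids in the first
#' column.
#' @rdname io
#' @export
readTimeseries <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df[[1]], NULL)
  m
}

#' @rdname io
#' @export
writeCircuits <- function(circuits, file) {
  payload <- list(
    circuits = circuits@circuits,
    merged_from = circuits@mergedFrom,
    provenance = circuits@provenance
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname io
#' @export
readCircuits <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  circuits <- lapply(payload$circuits, as.character)
  merged <- lapply(payload$merged_from, as.character)
  prov <- payload$provenance
  if (is.null(merged)) merged <- list()
  if (is.null(prov)) prov <- list()
  new("CircuitSet", circuits = circuits, mergedFrom = merged,
      provenance = lapply(prov, as.list))
}

#' Write a synthetic cohort to a directory
#'
#' Writes \code{participants.tsv}, \code{regions.tsv}, \code{coverage.tsv},
#' one \code{timeseries_<subject>.tsv} per subject (regions in rows,
#' header row of volume indices, region id in the first column) and
#' \code{truth.json} holding the planted schedules and rates.
#'
#' @rdname io
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(cohort@participants, "participants.tsv")
  tsv(cohort@regions, "regions.tsv")
  covDf <- data.frame(subject_id = rownames(cohort@coverage),
                      cohort@coverage, check.names = FALSE)
  tsv(covDf, "coverage.tsv")
  for (id in names(cohort@timeseries)) {
    m <- cohort@timeseries[[id]]
    df <- data.frame(region_id = rownames(m), m, check.names = FALSE)
    colnames(df) <- c("region_id", seq_len(ncol(m)))
    tsv(df, sprintf("timeseries_%s.tsv", id))
  }
  truth <- list(
    planted_group = as.list(cohort@truth$plantedGroup),
    switch_rate = as.list(cohort@truth$switchRate),
    n_events = lapply(cohort@truth$nEvents, unname),
    n_eligible = lapply(cohort@truth$nEligible, unname),
    schedules = lapply(cohort@schedules, function(s) list(
      base_allegiance = as.list(s@baseAllegiance),
      window_width = s@windowWidth,
      k_total = s@kTotal,
      transitions = lapply(s@transitions, function(ev) list(
        t = ev$t, regions = as.list(ev$regions),
        destination = ev$destination, mode = ev$mode))
    ))
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
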
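#' Validate a region table
#'
#' Checks the region bookkeeping table: unique region ids, a source in
#' {cortical, deep-gray} and exactly one resting-state-network label per
#' region. The reference configuration before quality control is 210
#' cortical plus 14 deep-gray regions.
#'
#' @param df data.frame with columns \code{region_id}, \code{name},
#'   \code{source}, \code{rsn_label}
#' @return The validated data.frame, invisibly augmented with an attribute
#'   \code{sourceCounts} (regions per source).
#' @export
regionTable <- function(df) {
  need <- c("region_id", "name", "source", "rsn_label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("region table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$region_id))
    stop("duplicate region ids: ",
         paste(unique(df$region_id[duplicated(df$region_id)]), collapse = ", "))
  if (!all(df$source %in% c("cortical", "deep-gray")))
    stop("source must be 'cortical' or 'deep-gray'")
  if (any(is.na(df$rsn_label)))
    stop("every region needs exactly one rsn_label")
  attr(df, "sourceCounts") <- table(df$source)
  df
}

.checkCoverage <- function(coverage) {
  coverage <- as.matrix(coverage)
  if (any(is.na(coverage))) {
    idx <- which(is.na(coverage), arr.ind = TRUE)[1, ]
    stop("missing coverage entry for subject '", rownames(coverage)[idx[1]],
         "', region '", colnames(coverage)[idx[2]], "'")
  }
  if (any(coverage < 0 | coverage > 1))
    stop("coverage fractions must lie in [0, 1]")
  coverage
}

#' Exclude participants with too many empty regions
#'
#' A participant is excluded when strictly more than \code{zeroRegionLimit}
#' regions have exactly zero voxel coverage. A subject with 12 zero-coverage
#' regions is retained; one with 13 is excluded.
#'
#' @param coverage subject-by-region matrix of coverage fractions in [0, 1],
#'   subject ids as rownames
#' @param zeroRegionLimit maximum tolerated count of zero-coverage regions
#'   (default 12)
#' @return list with \code{retained} (subject ids) and \code{exclusions}
#'   (data.frame subject_id, zero_regions, reason).
#' @export
excludeParticipants <- function(coverage, zeroRegionLimit = 12L) {
  coverage <- .checkCoverage(coverage)
  zeros <- rowSums(coverage == 0)
  out <- zeros > zeroRegionLimit
  list(
    retained = rownames(coverage)[!out],
    exclusions = data.frame(
      subject_id = rownames(coverage)[out],
      zero_regions = unname(zeros[out]),
      reason = rep(sprintf("more than %d zero-coverage regions",
                           zeroRegionLimit), sum(out))
    )
  )
}

#' Exclude poorly covered regions
#'
#' After participant exclusions, a region is excluded when the fraction of
#' retained subjects in which its coverage falls below \code{minCoverage} is
#' strictly greater than \code{maxSubjectFraction}. Both inequalities are
#' strict: coverage below 30\% in exactly 10\% of subjects retains the
#' region.
#'
#' @param coverage subject-by-region coverage matrix restricted to retained
#'   subjects
#' @param minCoverage per-subject coverage threshold (default 0.30)
#' @param maxSubjectFraction tolerated fraction of low-coverage subjects
#'   (default 0.10)
#' @return list with \code{retained} (region ids) and \code{exclusions}
#'   (data.frame region_id, low_coverage_fraction, reason).
#' @export
excludeRegions <- function(coverage, minCoverage = 0.30,
                           maxSubjectFraction = 0.10) {
  coverage <- .checkCoverage(coverage)
  if (nrow(coverage) == 0L) stop("empty subject set")
  lowFrac <- colMeans(coverage < minCoverage)
  out <- lowFrac > maxSubjectFraction
  list(
    retained = colnames(coverage)[!out],
    exclusions = data.frame(
      region_id = colnames(coverage)[out],
      low_coverage_fraction = unname(lowFrac[out]),
      reason = rep(sprintf("coverage < %g in > %g of participants",
                           minCoverage, maxSubjectFraction), sum(out))
    )
  )
}
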
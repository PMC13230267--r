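#' Normalize a density vector to its maximum
#'
#' Divides every regional receptor/transporter density by the maximum, for
#' cross-map comparability. Idempotent and scale-invariant; the output
#' maximum is exactly 1.
#'
#' @param raw named numeric vector, region id -> density; at least one value
#'   must be strictly positive
#' @return Named numeric vector with values in [0, 1] and max 1.
#' @export
normalizeDensity <- function(raw) {
  if (!is.numeric(raw) || length(raw) == 0L)
    stop("density must be a non-empty numeric vector")
  mx <- max(raw)
  if (mx <= 0)
    stop("density has no strictly positive value; cannot normalize")
  raw / mx
}

#' Locate the elbow of a sorted density curve
#'
#' Sorts densities in decreasing order and finds the point of maximum
#' perpendicular distance from the chord joining the first and last sorted
#' values, after scaling both the rank axis and the value axis to [0, 1]
#' (so the distance is expressed relative to the value range). The returned
#' \code{cutoffRank} is 1-based and inclusive: circuit members are the
#' regions at ranks 1..cutoffRank.
#'
#' When the maximum distance is below \code{linearityThreshold} (2\% of the
#' normalized range by default) the curve is declared linear
#' (\code{isLinear = TRUE}) and the caller should fall back to a top-fraction
#' selection.
#'
#' @param density named numeric vector of regional densities
#' @param linearityThreshold maximum chord distance (normalized units) below
#'   which the slope counts as linear (default 0.02)
#' @return list with \code{cutoffRank}, \code{isLinear}, \code{maxDistance},
#'   \code{distances} (per sorted rank) and \code{order} (region ids in
#'   decreasing density order, ties broken by region id).
#' @export
detectElbow <- function(density, linearityThreshold = 0.02) {
  n <- length(density)
  if (n < 3L) stop("elbow detection needs at least 3 regions")
  ids <- names(density)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(-density, ids)
  y <- as.numeric(density[ord])
  rng <- y[1] - y[n]
  if (rng == 0) {
    return(list(cutoffRank = 1L, isLinear = TRUE, maxDistance = 0,
                distances = rep(0, n), order = ids[ord]))
  }
  x <- (seq_len(n) - 1) / (n - 1)
  yn <- (y - y[n]) / rng
  # chord runs from (0, 1) to (1, 0): line x + y - 1 = 0; signed > 0 above
  signed <- x + yn - 1
  d <- abs(signed) / sqrt(2)
  maxd <- max(d)
  cutoff <- which.max(d)
  # when the chord crossing falls inside a cliff (the max-distance point
  # lies below the chord but its predecessor lies above), the cutoff is the
  # last region above the crossing, not the first one after the drop
  if (cutoff > 1L && signed[cutoff] < 0 && signed[cutoff - 1L] > 0)
    cutoff <- cutoff - 1L
  list(
    cutoffRank = cutoff,
    isLinear = maxd < linearityThreshold,
    maxDistance = maxd,
    distances = d,
    order = ids[ord]
  )
}

#' Select the top fraction of regions by density
#'
#' Returns the \code{ceiling(fraction * n)} highest-density regions; ties
#' are broken by region id order so the selection is deterministic. With 224
#' regions and the default fraction 0.05 this selects 12 regions.
#'
#' @param density named numeric vector of regional densities
#' @param fraction fraction of regions to keep, in (0, 1) (default 0.05)
#' @return Character vector of selected region ids, in decreasing density
#'   order.
#' @export
selectTopFraction <- function(density, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n <- length(density)
  ids <- names(density)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  k <- as.integer(ceiling(fraction * n))
  ids[order(-density, ids)][seq_len(k)]
}

#' Delineate monoaminergic circuits from density maps
#'
#' For each receptor/transporter map: restrict to the retained regions,
#' normalize to the maximum, locate the elbow of the sorted density curve
#' and keep the regions above it; when the curve is linear, fall back to the
#' top \code{fraction} of regions. Maps that select identical member sets
#' are merged into one jointly named circuit ("D2/DAT"-style).
#'
#' @param densities named list of named numeric density vectors, one per map
#' @param retainedRegions region ids that survived coverage quality control;
#'   selection happens after restriction to these
#' @param fraction top-fraction fallback for linear slopes (default 0.05)
#' @param linearityThreshold passed to [detectElbow()]
#' @return A [CircuitSet-class].
#' @export
buildCircuits <- function(densities, retainedRegions, fraction = 0.05,
                          linearityThreshold = 0.02) {
  if (is.null(names(densities)) || anyDuplicated(names(densities)))
    stop("densities must be a named list with unique map names")
  members <- list()
  prov <- list()
  for (map in names(densities)) {
    d <- densities[[map]]
    d <- d[names(d) %in% retainedRegions]
    if (length(d) < 3L)
      stop("map '", map, "': fewer than 3 retained regions")
    d <- normalizeDensity(d)
    eb <- detectElbow(d, linearityThreshold)
    if (eb$isLinear) {
      sel <- selectTopFraction(d, fraction)
      prov[[map]] <- list(method = "top-fraction", fraction = fraction,
                          nSelected = length(sel))
    } else {
      sel <- eb$order[seq_len(eb$cutoffRank)]
      prov[[map]] <- list(method = "elbow", cutoffRank = eb$cutoffRank,
                          maxDistance = eb$maxDistance)
    }
    if (length(sel) == 0L) stop("map '", map, "': empty circuit")
    members[[map]] <- sel
  }
  # merge maps with identical member sets under a joint "/" name
  keys <- vapply(members, function(x) paste(sort(x), collapse = "\r"),
                 character(1))
  circuits <- list(); mergedFrom <- list(); provenance <- list()
  for (key in unique(keys)) {
    maps <- names(members)[keys == key]
    joint <- paste(maps, collapse = "/")
    circuits[[joint]] <- members[[maps[1]]]
    provenance[[joint]] <- prov[[maps[1]]]
    if (length(maps) > 1L) mergedFrom[[joint]] <- maps
  }
  new("CircuitSet", circuits = circuits, mergedFrom = mergedFrom,
      provenance = provenance)
}
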
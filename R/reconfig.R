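.labelMatrix <- function(labels) {
  if (is(labels, "AllegianceMatrix")) labels@labels
  else as.matrix(labels)
}

#' Flexibility: fraction of transitions with an allegiance switch
#'
#' For each region, the number of window transitions at which its network
#' label changes, divided by the number of transitions (W - 1).
#'
#' @param labels an [AllegianceMatrix-class] or integer region-by-window
#'   matrix
#' @return Named numeric vector, one value in [0, 1] per region.
#' @export
flexibility <- function(labels) {
  lab <- .labelMatrix(labels)
  w <- ncol(lab)
  if (w < 2L) stop("flexibility needs at least 2 windows")
  rowMeans(lab[, -1L, drop = FALSE] != lab[, -w, drop = FALSE])
}

#' Promiscuity: fraction of networks visited
#'
#' Number of distinct network labels in a region's row divided by the total
#' number of networks K.
#'
#' @inheritParams flexibility
#' @param kTotal total number of networks (default 8)
#' @return Named numeric vector, one value in [1/K, 1] per region.
#' @export
promiscuity <- function(labels, kTotal = 8L) {
  lab <- .labelMatrix(labels)
  if (kTotal < max(lab)) stop("kTotal smaller than the largest label")
  apply(lab, 1L, function(r) length(unique(r))) / kTotal
}

#' Classify each switch as cohesive or disjoint
#'
#' At each window transition, a switching region's move is cohesive when at
#' least one other region switches at the same transition to the same
#' destination network; otherwise it is disjoint. Non-switching regions are
#' "none". Two regions switching simultaneously to different destinations
#' are both disjoint.
#'
#' @inheritParams flexibility
#' @return Character matrix (regions x transitions) with entries "none",
#'   "cohesive" or "disjoint".
#' @export
classifySwitches <- function(labels) {
  lab <- .labelMatrix(labels)
  w <- ncol(lab)
  if (w < 2L) stop("switch classification needs at least 2 windows")
  out <- matrix("none", nrow(lab), w - 1L,
                dimnames = list(rownames(lab), NULL))
  for (t in seq_len(w - 1L)) {
    switched <- lab[, t + 1L] != lab[, t]
    if (!any(switched)) next
    dest <- lab[switched, t + 1L]
    shared <- table(dest)
    cohesive <- as.integer(names(shared)[shared >= 2L])
    out[switched, t] <- ifelse(dest %in% cohesive, "cohesive", "disjoint")
  }
  out
}

#' Cohesion and disjointedness fractions
#'
#' Per region: the number of cohesive (resp. disjoint) switches divided by
#' the number of window transitions. Every switch is either cohesive or
#' disjoint, so cohesion + disjointedness = flexibility for every region --
#' exactly at the switch-count level, and to within a unit of
#' double-precision rounding on the stored fractions.
#'
#' @inheritParams flexibility
#' @return A list with named numeric vectors \code{cohesion} and
#'   \code{disjointedness}.
#' @export
cohesionDisjointedness <- function(labels) {
  cls <- classifySwitches(labels)
  nt <- ncol(cls)
  list(
    cohesion = rowSums(cls == "cohesive") / nt,
    disjointedness = rowSums(cls == "disjoint") / nt
  )
}

#' Aggregate region metrics per circuit and globally
#'
#' Unweighted means of region-level reconfiguration metrics over each
#' circuit's members and over all retained regions ("global").
#'
#' @param regionMetrics data.frame with column \code{region_id} and one
#'   column per metric (as produced by [reconfigureSubject()])
#' @param circuits a [CircuitSet-class], or NULL for global only
#' @param retainedRegions region ids entering the global average; defaults
#'   to all rows of \code{regionMetrics}
#' @return data.frame with columns \code{level} ("global" or "circuit"),
#'   \code{unit} and one column per metric.
#' @export
aggregateReconfig <- function(regionMetrics, circuits = NULL,
                              retainedRegions = regionMetrics$region_id) {
  stopifnot("region_id" %in% names(regionMetrics))
  metricCols <- setdiff(names(regionMetrics), "region_id")
  rows <- list()
  glob <- regionMetrics[regionMetrics$region_id %in% retainedRegions, ,
                        drop = FALSE]
  if (nrow(glob) == 0L) stop("no retained regions in metrics table")
  rows[[1]] <- data.frame(level = "global", unit = "global",
                          t(colMeans(glob[metricCols])))
  if (!is.null(circuits)) {
    for (nm in circuitNames(circuits)) {
      members <- circuitMembers(circuits, nm)
      if (!all(members %in% retainedRegions))
        stop("circuit '", nm, "' contains regions outside the retained set")
      sub <- regionMetrics[regionMetrics$region_id %in% members, ,
                           drop = FALSE]
      if (nrow(sub) == 0L) stop("circuit '", nm, "' is empty")
      rows[[length(rows) + 1L]] <- data.frame(level = "circuit", unit = nm,
                                              t(colMeans(sub[metricCols])))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
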
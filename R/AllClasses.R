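#' @import methods
NULL

#' Canonical resting-state network labels
#'
#' Eight fixed communities used for window-wise allegiance assignment: the
#' seven canonical cortical resting-state networks plus deep gray matter.
#'
#' @return Character vector of length 8.
#' @export
rsnLevels <- function() {
  c("VIS", "SMN", "DAN", "VAN", "LIM", "FPN", "DMN", "DGM")
}

#' Sliding-window plan over a BOLD time series
#'
#' Rectangular windows of fixed \code{width} at stride \code{step}, stored as
#' 1-based inclusive start indices. The number of windows is
#' \code{floor((nVolumes - width) / step) + 1}.
#'
#' @slot nVolumes total number of volumes covered by the plan
#' @slot width window width in volumes
#' @slot step stride between consecutive window starts, in volumes
#' @slot starts integer vector of 1-based window start indices
#'
#' @seealso [makeWindows()]
#' @export
setClass("WindowPlan",
  representation(
    nVolumes = "integer",
    width = "integer",
    step = "integer",
    starts = "integer"
  )
)

setValidity("WindowPlan", function(object) {
  n <- object@nVolumes; w <- object@width; s <- object@step
  if (length(n) != 1L || length(w) != 1L || length(s) != 1L)
    return("nVolumes, width and step must be scalars")
  if (w < 2L) return("width must be at least 2")
  if (s < 1L) return("step must be at least 1")
  if (w > n) return("width exceeds nVolumes")
  expected <- as.integer((n - w) %/% s + 1L)
  if (length(object@starts) != expected)
    return(sprintf("expected %d windows, found %d", expected,
                   length(object@starts)))
  if (!identical(object@starts, seq.int(1L, by = s,
                                        length.out = expected)))
    return("starts must be a regular 1-based sequence at stride step")
  TRUE
})

#' Functional connectivity matrix
#'
#' A symmetric region-by-region matrix produced by the static or windowed
#' transform chain. The diagonal is NA: self-connectivity is excluded from
#' every summary. \code{transformLog} records the transforms applied, in
#' order.
#'
#' @slot values symmetric numeric matrix, NA diagonal
#' @slot kind either "static" or "windowed"
#' @slot transformLog character vector naming applied transforms in order
#'
#' @seealso [staticFC()], [windowedFC()]
#' @export
setClass("FCMatrix",
  representation(
    values = "matrix",
    kind = "character",
    transformLog = "character"
  )
)

setValidity("FCMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (!object@kind %in% c("static", "windowed"))
    return("kind must be 'static' or 'windowed'")
  if (!all(is.na(diag(v)))) return("diagonal must be NA")
  off <- v[upper.tri(v)]
  tv <- t(v)
  if (!isTRUE(all.equal(off, tv[upper.tri(tv)], tolerance = 1e-12)))
    return("values must be symmetric")
  if (any(off < 0)) return("off-diagonal values must be non-negative")
  TRUE
})

#' Window-wise network allegiance labels
#'
#' Integer matrix of region-by-window resting-state-network assignments
#' (labels 1..K), with the window plan that produced it.
#'
#' @slot labels integer matrix, regions in rows, windows in columns
#' @slot kTotal total number of networks K
#' @slot plan the [WindowPlan-class] used
#'
#' @seealso [assignAllegiance()]
#' @export
setClass("AllegianceMatrix",
  representation(
    labels = "matrix",
    kTotal = "integer",
    plan = "WindowPlan"
  )
)

setValidity("AllegianceMatrix", function(object) {
  lab <- object@labels
  k <- object@kTotal
  if (length(k) != 1L || k < 1L) return("kTotal must be a positive scalar")
  if (!is.numeric(lab)) return("labels must be numeric")
  if (any(lab != as.integer(lab))) return("labels must be integers")
  if (any(lab < 1L | lab > k))
    return(sprintf("labels must lie in 1..%d", k))
  if (ncol(lab) != length(object@plan@starts))
    return("number of label columns must equal number of windows in plan")
  TRUE
})

#' Named circuits of brain regions
#'
#' Monoaminergic circuits as named lists of region identifiers. Circuits
#' whose member sets coincide are merged under a joint "A/B" name;
#' \code{mergedFrom} records the source maps of each merged circuit, and
#' \code{provenance} records per circuit how the cut-off was chosen
#' ("elbow" with its rank, or "top-fraction" fallback).
#'
#' @slot circuits named list of character vectors of region ids
#' @slot mergedFrom named list: joint name -> character vector of source maps
#' @slot provenance named list of per-circuit selection records
#'
#' @seealso [buildCircuits()]
#' @export
setClass("CircuitSet",
  representation(
    circuits = "list",
    mergedFrom = "list",
    provenance = "list"
  )
)

setValidity("CircuitSet", function(object) {
  cs <- object@circuits
  if (length(cs) == 0L) return("at least one circuit required")
  if (is.null(names(cs)) || anyDuplicated(names(cs)))
    return("circuits must have unique names")
  if (!all(vapply(cs, is.character, logical(1))))
    return("circuit members must be character region ids")
  if (any(vapply(cs, length, integer(1)) == 0L))
    return("empty circuit not allowed")
  sets <- lapply(cs, function(x) sort(unique(x)))
  for (i in seq_along(sets)) for (j in seq_len(i - 1L))
    if (identical(sets[[i]], sets[[j]]))
      return(sprintf("circuits '%s' and '%s' have identical member sets and must be merged",
                     names(cs)[j], names(cs)[i]))
  TRUE
})

#' Planted switching schedule for one synthetic subject
#'
#' Ground truth for the reconfiguration pipeline: a base network allegiance
#' per region plus a list of switching events. Each event names a window
#' transition t (1-based, between windows t and t+1), the regions that move,
#' one shared destination network, and a mode: "cohesive" events move two or
#' more regions together, "disjoint" events move exactly one.
#'
#' A switch at transition t is realized in the raw series at volume
#' t + width - 1 (first changed volume).
#'
#' @slot baseAllegiance named integer vector, region id -> network label 1..K
#' @slot transitions list of event lists with fields \code{t},
#'   \code{regions}, \code{destination}, \code{mode}
#' @slot kTotal number of networks K
#' @slot windowWidth window width the schedule is expressed against
#'
#' @seealso [switchSchedule()], [generateTimeseries()], [windowTruth()]
#' @export
setClass("SwitchSchedule",
  representation(
    baseAllegiance = "integer",
    transitions = "list",
    kTotal = "integer",
    windowWidth = "integer"
  )
)

setValidity("SwitchSchedule", function(object) {
  base <- object@baseAllegiance
  k <- object@kTotal
  if (is.null(names(base)) || anyDuplicated(names(base)))
    return("baseAllegiance must be named with unique region ids")
  if (any(base < 1L | base > k))
    return(sprintf("base allegiance labels must lie in 1..%d", k))
  if (object@windowWidth < 2L) return("windowWidth must be at least 2")
  # replay events in time order to validate against current allegiance
  ord <- order(vapply(object@transitions, `[[`, numeric(1), "t"))
  current <- base
  for (idx in ord) {
    ev <- object@transitions[[idx]]
    need <- c("t", "regions", "destination", "mode")
    if (!all(need %in% names(ev)))
      return(sprintf("transition %d lacks fields %s", idx,
                     paste(setdiff(need, names(ev)), collapse = ", ")))
    if (ev$t < 1L)
      return(sprintf("transition %d: index %d out of range", idx, ev$t))
    if (!ev$mode %in% c("cohesive", "disjoint"))
      return(sprintf("transition %d: unknown mode '%s'", idx, ev$mode))
    if (ev$mode == "disjoint" && length(ev$regions) != 1L)
      return(sprintf("transition %d: a disjoint event names exactly one region", idx))
    if (ev$mode == "cohesive" && length(ev$regions) < 2L)
      return(sprintf("transition %d: a cohesive event names at least two regions", idx))
    if (!all(ev$regions %in% names(base)))
      return(sprintf("transition %d: unknown region id", idx))
    if (ev$destination < 1L || ev$destination > k)
      return(sprintf("transition %d: destination out of 1..%d", idx, k))
    if (any(current[ev$regions] == ev$destination))
      return(sprintf("transition %d: destination equals current allegiance of a named region", idx))
    current[ev$regions] <- as.integer(ev$destination)
  }
  TRUE
})

#' Specification of a synthetic fatigue cohort
#'
#' Study conditions for [generateCohort()]: group sizes for healthy controls
#' and the three MS fatigue groups, region/volume counts, per-group planted
#' switch rates, noise amplitude, covariate distributions and FSMC score
#' ranges. Group order throughout: HC, none, mild/moderate, severe.
#'
#' @slot nPerGroup named integer vector of group sizes
#' @slot nRegions number of regions
#' @slot nVolumes number of volumes per subject
#' @slot nRSN number of resting-state networks
#' @slot windowWidth window width against which switches are planted
#' @slot switchRate named numeric vector per group: expected allegiance
#'   switches per mobile region per clear transition. Switching is realized
#'   as transient visits (departure plus matched return, each one switch),
#'   so visits start at rate switchRate/2.
#' @slot cohesiveFraction target probability that a departure has at least
#'   one same-network co-mover (co-movers share destination and return
#'   time, making their switches cohesive)
#' @slot noiseSd within-region noise standard deviation (latent signals have
#'   unit variance)
#' @slot ageMean,ageSd,eduMean,eduSd,sexFemaleProp per-group covariate
#'   distribution parameters
#' @slot fsmcRange named list of length-2 total-score ranges per group
#' @slot seed integer seed fully determining the cohort
#' @export
setClass("CohortSpec",
  representation(
    nPerGroup = "integer",
    nRegions = "integer",
    nVolumes = "integer",
    nRSN = "integer",
    windowWidth = "integer",
    switchRate = "numeric",
    cohesiveFraction = "numeric",
    noiseSd = "numeric",
    ageMean = "numeric",
    ageSd = "numeric",
    eduMean = "numeric",
    eduSd = "numeric",
    sexFemaleProp = "numeric",
    fsmcRange = "list",
    seed = "integer"
  )
)

.cohortGroups <- function() c("HC", "none", "mild/moderate", "severe")

setValidity("CohortSpec", function(object) {
  gs <- .cohortGroups()
  for (slotname in c("nPerGroup", "switchRate", "ageMean", "ageSd", "eduMean",
                     "eduSd", "sexFemaleProp", "fsmcRange")) {
    v <- slot(object, slotname)
    if (!identical(names(v), gs))
      return(sprintf("%s must be named by groups %s", slotname,
                     paste(gs, collapse = ", ")))
  }
  if (any(object@nPerGroup < 0L)) return("group sizes must be non-negative")
  if (object@nRSN < 2L) return("need at least 2 networks")
  if (object@nRegions < 3L * object@nRSN)
    return("need at least 3 regions per network")
  if (object@nVolumes < object@windowWidth)
    return("nVolumes must be at least the window width")
  if (any(object@switchRate < 0 | object@switchRate > 1))
    return("switch rates must lie in [0, 1]")
  if (object@cohesiveFraction < 0 || object@cohesiveFraction > 1)
    return("cohesiveFraction must lie in [0, 1]")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  if (any(object@sexFemaleProp < 0 | object@sexFemaleProp > 1))
    return("sex proportions must lie in [0, 1]")
  # FSMC ranges must not straddle the analysis-group cut-offs they must produce
  for (g in gs) {
    r <- object@fsmcRange[[g]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0 || r[2] > 100)
      return(sprintf("fsmcRange for '%s' must be an ordered pair in [0, 100]", g))
    target <- if (g == "HC") "none" else g
    lo <- fatigueGroup(r[1], "total"); hi <- fatigueGroup(r[2], "total")
    if (lo != target || hi != target)
      return(sprintf("fsmcRange for '%s' straddles a fatigue cut-off (classifies as %s..%s)",
                     g, lo, hi))
  }
  TRUE
})

#' A generated synthetic cohort
#'
#' Output container of [generateCohort()]: the participant table, region
#' table, per-subject time-series matrices and coverage fractions, plus the
#' planted ground truth (schedules and rates) that tests recover.
#'
#' @slot spec the [CohortSpec-class] used
#' @slot participants data.frame, one row per subject
#' @slot regions data.frame region table (region_id, name, source, rsn_label)
#' @slot timeseries named list of region-by-volume matrices (may be empty
#'   when generated with \code{timeseries = FALSE})
#' @slot coverage subject-by-region matrix of coverage fractions
#' @slot schedules named list of [SwitchSchedule-class] per subject
#' @slot truth list of planted quantities (per-subject planted group, event
#'   counts, eligible transition counts)
#' @export
setClass("SyntheticCohort",
  representation(
    spec = "CohortSpec",
    participants = "data.frame",
    regions = "data.frame",
    timeseries = "list",
    coverage = "matrix",
    schedules = "list",
    truth = "list"
  )
)
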
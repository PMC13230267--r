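# run expr under a temporary seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

#' Construct a planted switching schedule
#'
#' @param baseAllegiance named integer vector, region id -> network label
#'   1..kTotal
#' @param transitions list of events; each event is a list with fields
#'   \code{t} (window transition index, 1-based), \code{regions} (region
#'   ids), \code{destination} (network label) and \code{mode} ("cohesive"
#'   for two or more regions moving together, "disjoint" for a single
#'   region)
#' @param kTotal number of networks
#' @param windowWidth window width the transition indices refer to
#' @return A validated [SwitchSchedule-class]; an inconsistent schedule
#'   fails with a message naming the offending transition.
#' @export
switchSchedule <- function(baseAllegiance, transitions = list(),
                           kTotal = 8L, windowWidth = 27L) {
  new("SwitchSchedule",
      baseAllegiance = structure(as.integer(baseAllegiance),
                                 names = names(baseAllegiance)),
      transitions = transitions,
      kTotal = as.integer(kTotal),
      windowWidth = as.integer(windowWidth))
}

# allegiance per region per volume implied by a schedule: a switch at window
# transition t first affects volume t + width - 1
.volumeAllegiance <- function(schedule, nVolumes) {
  base <- schedule@baseAllegiance
  out <- matrix(rep(base, nVolumes), nrow = length(base),
                dimnames = list(names(base), NULL))
  ord <- order(vapply(schedule@transitions, `[[`, numeric(1), "t"))
  for (ev in schedule@transitions[ord]) {
    v0 <- ev$t + schedule@windowWidth - 1L
    if (v0 <= nVolumes)
      out[ev$regions, v0:nVolumes] <- as.integer(ev$destination)
  }
  out
}

#' Generate a synthetic region-by-volume BOLD series
#'
#' Each network has an independent unit-variance Gaussian latent signal
#' (white noise per volume). A region's signal at volume v is the latent
#' signal of its current network allegiance plus independent Gaussian noise
#' of standard deviation \code{noiseSd}. A switch planted at window
#' transition t changes the region's latent source from volume
#' t + width - 1 onward.
#'
#' @param schedule a [SwitchSchedule-class]
#' @param nVolumes number of volumes to generate (at least 2)
#' @param noiseSd noise standard deviation in latent-signal units
#' @param seed optional integer; when given, output is a deterministic
#'   function of (schedule, nVolumes, noiseSd, seed) and the caller's RNG
#'   state is untouched
#' @return Numeric matrix, regions in rows (named), volumes in columns.
#' @export
generateTimeseries <- function(schedule, nVolumes, noiseSd = 0.5,
                               seed = NULL) {
  if (!is.null(seed))
    return(withSeed(seed,
                    generateTimeseries(schedule, nVolumes, noiseSd)))
  validObject(schedule)
  nVolumes <- as.integer(nVolumes)
  if (nVolumes < 2L) stop("need at least 2 volumes")
  alleg <- .volumeAllegiance(schedule, nVolumes)
  k <- schedule@kTotal
  latent <- matrix(stats::rnorm(k * nVolumes), k, nVolumes)
  idx <- cbind(as.vector(alleg),
               rep(seq_len(nVolumes), each = nrow(alleg)))
  sig <- matrix(latent[idx], nrow(alleg), nVolumes,
                dimnames = dimnames(alleg))
  if (noiseSd > 0)
    sig <- sig + matrix(stats::rnorm(length(sig), sd = noiseSd),
                        nrow(sig), ncol(sig))
  sig
}

#' Ground-truth window-domain allegiance
#'
#' The planted allegiance of each region in each window of \code{plan}:
#' the region's label when the window's volume span lies entirely within one
#' allegiance epoch, and NA for boundary windows that straddle a planted
#' switch. Recovery tests compare only non-NA entries.
#'
#' @param schedule a [SwitchSchedule-class]
#' @param plan a [WindowPlan-class]
#' @return Integer matrix (regions x windows) with NA at boundary windows.
#' @export
windowTruth <- function(schedule, plan) {
  alleg <- .volumeAllegiance(schedule, plan@nVolumes)
  nw <- nWindows(plan)
  out <- matrix(NA_integer_, nrow(alleg), nw,
                dimnames = list(rownames(alleg), NULL))
  for (w in seq_len(nw)) {
    span <- alleg[, .windowIndices(plan, w), drop = FALSE]
    const <- span[, 1L]
    pure <- rowSums(span != const) == 0L
    out[pure, w] <- const[pure]
  }
  out
}

#' Flexibility restricted to interior windows
#'
#' Flexibility estimated after removing each region's boundary windows
#' (those straddling a planted switch, NA in \code{truth}): switches are
#' counted between consecutive retained windows and divided by the number of
#' retained transitions. This is the boundary-corrected estimate used for
#' planted-rate recovery: each planted event appears as exactly one switch
#' between its flanking interior windows.
#'
#' @param alleg recovered [AllegianceMatrix-class] (or label matrix)
#' @param truth matrix from [windowTruth()], same shape
#' @return data.frame with per-region \code{switches} and
#'   \code{transitions} counts.
#' @export
interiorFlexibility <- function(alleg, truth) {
  lab <- .labelMatrix(alleg)
  stopifnot(all(dim(lab) == dim(truth)))
  sw <- integer(nrow(lab)); tr <- integer(nrow(lab))
  for (i in seq_len(nrow(lab))) {
    keep <- !is.na(truth[i, ])
    row <- lab[i, keep]
    tr[i] <- length(row) - 1L
    sw[i] <- sum(row[-1L] != row[-length(row)])
  }
  data.frame(region_id = rownames(lab), switches = sw, transitions = tr,
             row.names = NULL)
}

#' Generate a synthetic density vector with a planted elbow
#'
#' Produces regional densities whose sorted curve has a knee at rank
#' \code{nTop}: a steep linear segment over the top \code{nTop} ranks
#' followed by a gently decaying tail whose per-rank drop stays below the
#' chord's per-rank drop, so the point of maximum perpendicular distance
#' from the chord is exactly rank \code{nTop}. \code{elbowSharpness} = 1
#' produces a linear decreasing ramp with no elbow (the top-fraction
#' fallback case); larger values deepen the knee. A small seeded jitter
#' (sd 5e-4) perturbs values without disturbing the planted ranking.
#'
#' @param nRegions number of regions
#' @param nTop planted circuit size (2 <= nTop < nRegions)
#' @param elbowSharpness knee depth; 1 = linear, >= 2 gives a knee the
#'   detector recovers exactly
#' @param seed integer seed
#' @return Named numeric vector normalized to max 1, with attribute
#'   \code{topRegions} naming the planted members.
#' @export
generateDensity <- function(nRegions, nTop, elbowSharpness = 5, seed = 1L) {
  n <- as.integer(nRegions)
  if (nTop >= n) stop("nTop must be smaller than nRegions")
  if (nTop < 2L) stop("nTop must be at least 2")
  if (elbowSharpness < 1) stop("elbowSharpness must be >= 1")
  tEnd <- 0.05
  withSeed(seed, {
    if (elbowSharpness == 1) {
      y <- seq(1, tEnd, length.out = n)
    } else {
      chordAtTop <- 1 - (1 - tEnd) * (nTop - 1) / (n - 1)
      yK <- chordAtTop - (1 - 1 / elbowSharpness) * (chordAtTop - tEnd)
      seg1 <- seq(1, yK, length.out = nTop)
      # tail: geometric decay whose first step is 70% of the chord's
      # per-rank drop, keeping the max-distance point at rank nTop
      g1 <- 0.7 * (1 - tEnd) / (n - 1)
      r <- 1 - g1 / (yK - tEnd)
      r <- min(max(r, 0.5), 0.9999)
      tail <- tEnd + (yK - tEnd) * r^(seq_len(n - nTop))
      y <- c(seg1, tail)
    }
    y <- sort(y + stats::rnorm(n, sd = 5e-4), decreasing = TRUE)
    y <- pmax(y, 1e-6)
    ids <- sprintf("R%03d", seq_len(n))
    perm <- sample.int(n)
    out <- numeric(n)
    names(out) <- ids
    out[perm] <- y  # region perm[rank] carries the rank-th value
    out <- out / max(out)
    attr(out, "topRegions") <- sort(ids[perm[seq_len(nTop)]])
    out
  })
}

#' Synthetic coverage matrix for quality-control fixtures
#'
#' All-ones coverage except that \code{nFailing} regions are given coverage
#' 0.2 in just enough subjects to strictly exceed the 10\% low-coverage
#' rule, and one additional boundary region gets low coverage in exactly
#' 10\% of subjects (retained under the strict inequality).
#'
#' @param nSubjects number of subjects (must be a multiple of 10 so the
#'   boundary case is exact)
#' @param nRegions number of regions
#' @param nFailing number of regions built to fail the rule
#' @param seed integer seed choosing which regions fail
#' @return Subject-by-region matrix of coverage fractions.
#' @export
generateCoverageFixture <- function(nSubjects = 20L, nRegions = 224L,
                                    nFailing = 22L, seed = 1L) {
  if (nSubjects %% 10L != 0L)
    stop("nSubjects must be a multiple of 10")
  if (nFailing + 1L > nRegions)
    stop("nFailing too large for nRegions")
  withSeed(seed, {
    cov <- matrix(1, nSubjects, nRegions,
                  dimnames = list(sprintf("P%03d", seq_len(nSubjects)),
                                  sprintf("R%03d", seq_len(nRegions))))
    failing <- sample.int(nRegions, nFailing + 1L)
    boundary <- failing[nFailing + 1L]
    nOver <- nSubjects %/% 10L + 1L  # strictly more than 10%
    for (r in failing[seq_len(nFailing)])
      cov[sample.int(nSubjects, nOver), r] <- 0.2
    cov[sample.int(nSubjects, nSubjects %/% 10L), boundary] <- 0.2
    attr(cov, "failingRegions") <- sort(colnames(cov)[failing[seq_len(nFailing)]])
    attr(cov, "boundaryRegion") <- colnames(cov)[boundary]
    cov
  })
}
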
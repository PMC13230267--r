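#' Specify a synthetic fatigue cohort
#'
#' Constructor for [CohortSpec-class] with defaults mirroring a realistic MS
#' fatigue cohort: four groups (60 healthy controls; 87 non-fatigued, 77
#' mildly/moderately fatigued and 53 severely fatigued people with MS), 224
#' regions by 300 volumes, 8 networks, window width 27, and covariate
#' distributions (age, education, sex) typical of such samples. The planted switch-rate difference between the severe
#' and HC groups defaults to 0.015 per eligible transition, the order of
#' magnitude of circuit-flexibility group differences reported in the MS
#' fatigue literature.
#'
#' @param nPerGroup named integer vector of group sizes (names HC, none,
#'   mild/moderate, severe)
#' @param nRegions,nVolumes,nRSN,windowWidth cohort geometry
#' @param switchRate planted expected switches per mobile region per clear
#'   transition, per group; realized as transient visits (see
#'   [CohortSpec-class])
#' @param cohesiveFraction target probability that a departure has at least
#'   one same-network co-mover
#' @param noiseSd within-region noise sd (latent signals have unit variance)
#' @param ageMean,ageSd,eduMean,eduSd,sexFemaleProp per-group covariate
#'   parameters
#' @param fsmcRange named list of length-2 FSMC total ranges per group; each
#'   range must fall inside the fatigue band its group must classify into
#' @param seed integer seed fully determining the cohort
#' @return A validated [CohortSpec-class].
#' @export
cohortSpec <- function(nPerGroup = c(HC = 60L, none = 87L,
                                     `mild/moderate` = 77L, severe = 53L),
                       nRegions = 224L, nVolumes = 300L, nRSN = 8L,
                       windowWidth = 27L,
                       switchRate = c(HC = 0.020, none = 0.022,
                                      `mild/moderate` = 0.028,
                                      severe = 0.035),
                       cohesiveFraction = 0.7, noiseSd = 0.5,
                       ageMean = c(HC = 30.46, none = 38.06,
                                   `mild/moderate` = 40.59, severe = 40.74),
                       ageSd = c(HC = 8.34, none = 8.97,
                                 `mild/moderate` = 11.34, severe = 11.07),
                       eduMean = c(HC = 17.41, none = 15.17,
                                   `mild/moderate` = 14.48, severe = 14.08),
                       eduSd = c(HC = 2.98, none = 3.34,
                                 `mild/moderate` = 3.63, severe = 3.30),
                       sexFemaleProp = c(HC = 0.567, none = 0.54,
                                         `mild/moderate` = 0.531,
                                         severe = 0.667),
                       fsmcRange = list(HC = c(20, 42), none = c(20, 42),
                                        `mild/moderate` = c(43, 62),
                                        severe = c(63, 96)),
                       seed = 1L) {
  gs <- .cohortGroups()
  fix <- function(v) {
    v <- v[gs]
    names(v) <- gs
    v
  }
  new("CohortSpec",
      nPerGroup = structure(as.integer(fix(nPerGroup)), names = gs),
      nRegions = as.integer(nRegions), nVolumes = as.integer(nVolumes),
      nRSN = as.integer(nRSN), windowWidth = as.integer(windowWidth),
      switchRate = fix(switchRate), cohesiveFraction = cohesiveFraction,
      noiseSd = noiseSd, ageMean = fix(ageMean), ageSd = fix(ageSd),
      eduMean = fix(eduMean), eduSd = fix(eduSd),
      sexFemaleProp = fix(sexFemaleProp),
      fsmcRange = fsmcRange[gs], seed = as.integer(seed))
}

# region table for a synthetic cohort: deep-gray regions carry the DGM
# network; cortical regions are assigned round-robin to the other networks
.syntheticRegions <- function(nRegions, nRSN) {
  nDeep <- max(3L, round(nRegions / 16))
  nCort <- nRegions - nDeep
  ids <- sprintf("R%03d", seq_len(nRegions))
  lv <- if (nRSN == 8L) rsnLevels() else
    c(sprintf("NET%d", seq_len(nRSN - 1L)), "DGM")
  rsn <- c(rep(lv[seq_len(nRSN - 1L)], length.out = nCort),
           rep(lv[nRSN], nDeep))
  data.frame(
    region_id = ids,
    name = c(sprintf("cortical_%03d", seq_len(nCort)),
             sprintf("deepgray_%02d", seq_len(nDeep))),
    source = c(rep("cortical", nCort), rep("deep-gray", nDeep)),
    rsn_label = rsn
  )
}

#' Map region-table network labels to integer codes
#'
#' @param regions region table (data.frame with \code{region_id} and
#'   \code{rsn_label})
#' @param levels label order defining codes 1..K (default [rsnLevels()])
#' @return Named integer vector region_id -> network code.
#' @export
regionRSNCodes <- function(regions, levels = rsnLevels()) {
  codes <- match(regions$rsn_label, levels)
  if (any(is.na(codes)))
    stop("unknown rsn_label: ",
         paste(unique(regions$rsn_label[is.na(codes)]), collapse = ", "))
  structure(as.integer(codes), names = regions$region_id)
}

# Draw one subject's switching events as transient visits: a region departs
# its home network at transition t and returns at t + dwell, so the fixed
# network structure that allegiance assignment relies on never dissolves.
# Departures are drawn inside network-level "slots": at each transition and
# network, a slot fires with probability pi, and every clear member of the
# network then departs independently with probability s, with pi * s =
# rate / 2. Each visit contributes two switches (out and back), so the
# expected number of switches per region per clear transition is exactly
# `rate`; co-departing members of one slot share destination and return
# time, making both their switches cohesive. s is set from
# cohesiveFraction, the target probability that a departure has at least
# one co-mover when all other members are clear. A region is clear when it
# is home and a full window width past its last return, and departures stop
# early enough that every visit has fully interior windows on both sides.
.drawSchedule <- function(rsnCodes, rate, cohesiveFraction,
                          nVolumes, width, kTotal) {
  W <- nVolumes - width + 1L
  dwell <- width + 3L
  tMax <- W - width - dwell
  nr <- length(rsnCodes)
  clearAt <- rep(2L, nr)  # earliest transition at which the region is clear
  nClear <- integer(nr)
  nSwitch <- integer(nr)
  transitions <- list()
  pDepart <- rate / 2
  # two thirds of each network's regions are anchors that never depart.
  # This keeps the allegiance argmax well conditioned: a network's faithful
  # anchors always outweigh (i) the visitor's co-moving home neighbours and
  # (ii) any cohesive group arriving from another network, whose members
  # transiently mimic their home network inside the destination. Both
  # bounds need the mobile pool to stay below half the anchored mass.
  anchors <- integer(0)
  for (k in seq_len(kTotal)) {
    members <- which(rsnCodes == k)
    m <- length(members)
    anchors <- c(anchors, members[seq_len(min(m - 1L, ceiling(2 * m / 3)))])
  }
  if (tMax >= 2L && pDepart > 0) {
    for (k in seq_len(kTotal)) {
      members <- setdiff(which(rsnCodes == k), anchors)
      m <- length(members)
      if (m == 0L) next
      s <- if (m > 1L && cohesiveFraction < 1)
        1 - (1 - cohesiveFraction)^(1 / (m - 1L)) else 1
      s <- min(max(s, pDepart), 1)
      piSlot <- pDepart / s
      for (t in 2:tMax) {
        clear <- members[clearAt[members] <= t]
        if (length(clear) == 0L) next
        nClear[clear] <- nClear[clear] + 1L
        if (stats::runif(1) >= piSlot) next
        movers <- clear[stats::runif(length(clear)) < s]
        if (length(movers) == 0L) next
        dest <- if (kTotal == 2L) setdiff(1:2, k) else
          sample(setdiff(seq_len(kTotal), k), 1L)
        mode <- if (length(movers) >= 2L) "cohesive" else "disjoint"
        transitions[[length(transitions) + 1L]] <- list(
          t = t, regions = names(rsnCodes)[movers],
          destination = as.integer(dest), mode = mode)
        transitions[[length(transitions) + 1L]] <- list(
          t = t + dwell, regions = names(rsnCodes)[movers],
          destination = as.integer(k), mode = mode)
        nSwitch[movers] <- nSwitch[movers] + 2L
        clearAt[movers] <- t + dwell + width
      }
    }
  }
  list(transitions = transitions, eligible = nClear, nEvents = nSwitch,
       anchors = names(rsnCodes)[anchors])
}

.clampRound <- function(x, lo, hi, digits = 0) {
  pmin(pmax(round(x, digits), lo), hi)
}

#' Generate a synthetic cohort
#'
#' Draws, per subject: covariates (sex, age, education), FSMC totals inside
#' the group's configured band (plus consistent cognitive/motor subscores),
#' HADS scores below the exclusion threshold, an MS phenotype for people
#' with MS, a planted switching schedule at the group's rate, and (unless
#' \code{timeseries = FALSE}) a region-by-volume BOLD series realizing the
#' schedule. Identical specs produce identical cohorts.
#'
#' @param spec a [CohortSpec-class]
#' @param timeseries generate the (large) time-series matrices? Set FALSE
#'   when only the participant table or schedules are needed.
#' @return A [SyntheticCohort-class].
#' @export
generateCohort <- function(spec, timeseries = TRUE) {
  validObject(spec)
  withSeed(spec@seed, {
    gs <- .cohortGroups()
    regions <- .syntheticRegions(spec@nRegions, spec@nRSN)
    lv <- unique(c(setdiff(regions$rsn_label, "DGM"), "DGM"))
    rsnCodes <- regionRSNCodes(regions, lv)
    rows <- list(); schedules <- list(); tsList <- list()
    planted <- character(0); nEvents <- list(); nEligible <- list()
    sid <- 0L
    for (g in gs) {
      for (j in seq_len(spec@nPerGroup[[g]])) {
        sid <- sid + 1L
        id <- sprintf("S%03d", sid)
        fr <- spec@fsmcRange[[g]]
        total <- sample(seq.int(fr[1], fr[2]), 1L)
        cogShare <- stats::runif(1, 0.45, 0.55)
        cog <- .clampRound(total * cogShare,
                           max(10, total - 50), min(50, total - 10))
        rows[[sid]] <- data.frame(
          subject_id = id,
          group = if (g == "HC") "HC" else "pwMS",
          sex = if (stats::runif(1) < spec@sexFemaleProp[[g]]) "F" else "M",
          age = .clampRound(stats::rnorm(1, spec@ageMean[[g]],
                                         spec@ageSd[[g]]), 18, 75, 1),
          education_years = .clampRound(
            stats::rnorm(1, spec@eduMean[[g]], spec@eduSd[[g]]), 8, 25, 1),
          fsmc_total = total,
          fsmc_cognitive = cog,
          fsmc_motor = total - cog,
          hads_a = sample(0:10, 1L),
          hads_d = sample(0:8, 1L),
          ms_type = if (g == "HC") NA_character_ else
            sample(c("RRMS", "PMS", "CIS"), 1L,
                   prob = c(0.894, 0.074, 0.032))
        )
        drawn <- .drawSchedule(rsnCodes, spec@switchRate[[g]],
                               spec@cohesiveFraction, spec@nVolumes,
                               spec@windowWidth, spec@nRSN)
        sch <- switchSchedule(rsnCodes, drawn$transitions, spec@nRSN,
                              spec@windowWidth)
        schedules[[id]] <- sch
        planted[id] <- g
        nEvents[[id]] <- drawn$nEvents
        nEligible[[id]] <- drawn$eligible
        if (timeseries)
          tsList[[id]] <- generateTimeseries(sch, spec@nVolumes,
                                             spec@noiseSd)
      }
    }
    participants <- do.call(rbind, rows)
    coverage <- matrix(1, nrow(participants), spec@nRegions,
                       dimnames = list(participants$subject_id,
                                       regions$region_id))
    new("SyntheticCohort", spec = spec, participants = participants,
        regions = regions, timeseries = tsList, coverage = coverage,
        schedules = schedules,
        truth = list(plantedGroup = planted,
                     switchRate = stats::setNames(spec@switchRate[planted],
                                                  names(planted)),
                     nEvents = nEvents, nEligible = nEligible))
  })
}
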
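test_that("time-series generation is deterministic and respects structure", {
  base <- setNames(rep(1:2, each = 3L), sprintf("R%d", 1:6))
  sched <- switchSchedule(base, kTotal = 2L, windowWidth = 27L)

  # noiseless shared signal: within-network correlation exactly 1
  ts <- generateTimeseries(sched, 50, noiseSd = 0, seed = 1)
  expect_equal(cor(ts["R1", ], ts["R2", ]), 1)
  expect_equal(cor(ts["R4", ], ts["R6", ]), 1)
  expect_lt(abs(cor(ts["R1", ], ts["R4", ])), 0.5)

  # determinism contract
  expect_identical(ts, generateTimeseries(sched, 50, noiseSd = 0, seed = 1))
  ts2 <- generateTimeseries(sched, 50, noiseSd = 0.3, seed = 9)
  expect_identical(ts2, generateTimeseries(sched, 50, noiseSd = 0.3, seed = 9))
  expect_false(identical(ts2, generateTimeseries(sched, 50, 0.3, seed = 10)))
})

test_that("inconsistent schedules fail validation naming the transition", {
  base <- setNames(rep(1:2, each = 2L), sprintf("R%d", 1:4))
  # destination equals current allegiance
  expect_error(
    switchSchedule(base, list(list(t = 3L, regions = "R1",
                                   destination = 1L, mode = "disjoint")),
                   kTotal = 2L),
    "transition 1")
  # cohesive event with a single region
  expect_error(
    switchSchedule(base, list(list(t = 3L, regions = "R1",
                                   destination = 2L, mode = "cohesive")),
                   kTotal = 2L),
    "at least two")
  # disjoint event naming two regions
  expect_error(
    switchSchedule(base, list(list(t = 3L, regions = c("R1", "R2"),
                                   destination = 2L, mode = "disjoint")),
                   kTotal = 2L),
    "exactly one")
})

test_that("a planted switch lands at the documented volume", {
  base <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), sprintf("R%d", 1:6))
  ev <- list(list(t = 5L, regions = "R1", destination = 2L,
                  mode = "disjoint"))
  sched <- switchSchedule(base, ev, kTotal = 2L, windowWidth = 10L)
  ts <- generateTimeseries(sched, 40, noiseSd = 0, seed = 4)
  v0 <- 5 + 10 - 1  # first changed volume
  expect_equal(ts["R1", 1:(v0 - 1)], ts["R2", 1:(v0 - 1)])
  expect_equal(ts["R1", v0:40], ts["R4", v0:40])
})

test_that("window truth marks boundary windows NA and epochs by label", {
  base <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), sprintf("R%d", 1:6))
  ev <- list(list(t = 5L, regions = "R1", destination = 2L,
                  mode = "disjoint"))
  sched <- switchSchedule(base, ev, kTotal = 2L, windowWidth = 10L)
  plan <- makeWindows(40, 10)
  tru <- windowTruth(sched, plan)
  v0 <- 14
  expect_true(all(tru["R1", 1:4] == 1))          # windows ending before v0
  expect_true(all(is.na(tru["R1", 5:(v0 - 1)]))) # straddling windows
  expect_true(all(tru["R1", v0:31] == 2))        # fully after
  expect_true(all(tru["R2", ] == 1))             # untouched region
})

test_that("density generator output is normalized with planted structure", {
  d <- generateDensity(224, 12, 5, seed = 1)
  expect_equal(max(d), 1)
  expect_true(all(d > 0 & d <= 1))
  expect_length(attr(d, "topRegions"), 12)
  expect_identical(d, generateDensity(224, 12, 5, seed = 1))
  expect_error(generateDensity(10, 10, 5), "smaller")
  expect_error(generateDensity(10, 12, 5), "smaller")
})

test_that("cohort generation is deterministic and honors group structure", {
  spec <- testCohortSpec(31, nPerGroup = c(HC = 3L, none = 2L,
                                           `mild/moderate` = 0L,
                                           severe = 3L))
  co <- generateCohort(spec, timeseries = FALSE)
  expect_equal(nrow(co@participants), 8)
  # empty group absent, others intact
  expect_equal(as.integer(table(co@truth$plantedGroup)[c("HC", "none", "severe")]),
               c(3L, 2L, 3L))
  expect_false("mild/moderate" %in% co@truth$plantedGroup)
  # FSMC totals classify back into the planted groups
  pw <- co@participants[co@participants$group == "pwMS", ]
  expect_equal(unname(fatigueGroup(pw$fsmc_total, "total")),
               unname(co@truth$plantedGroup[pw$subject_id]))
  # HC below every fatigue cut-off, HADS-D below the exclusion threshold
  hc <- co@participants[co@participants$group == "HC", ]
  expect_true(all(hc$fsmc_total < 43))
  expect_true(all(co@participants$hads_d < 11))

  co2 <- generateCohort(spec, timeseries = FALSE)
  expect_identical(co@participants, co2@participants)
  expect_equal(co@truth$nEvents, co2@truth$nEvents)

  spec3 <- testCohortSpec(32, nPerGroup = c(HC = 3L, none = 2L,
                                            `mild/moderate` = 0L,
                                            severe = 3L))
  co3 <- generateCohort(spec3, timeseries = FALSE)
  expect_false(identical(co@participants$age, co3@participants$age))
})

test_that("fsmc ranges straddling a cut-off are rejected", {
  expect_error(
    testCohortSpec(1, fsmcRange = list(HC = c(20, 42), none = c(20, 50),
                                       `mild/moderate` = c(43, 62),
                                       severe = c(63, 96))),
    "straddles")
})

test_that("cohort time series are reproducible end to end", {
  spec <- testCohortSpec(77, nPerGroup = c(HC = 1L, none = 0L,
                                           `mild/moderate` = 0L,
                                           severe = 1L),
                         nRegions = 32L, nVolumes = 60L)
  co <- generateCohort(spec)
  co2 <- generateCohort(spec)
  expect_identical(co@timeseries, co2@timeseries)
  expect_equal(dim(co@timeseries[[1]]), c(32L, 60L))
})

test_that("cohort files round-trip through the text formats", {
  spec <- testCohortSpec(5, nPerGroup = c(HC = 2L, none = 0L,
                                          `mild/moderate` = 0L,
                                          severe = 1L),
                         nRegions = 32L, nVolumes = 60L)
  co <- generateCohort(spec)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  p <- readParticipants(file.path(dir, "participants.tsv"))
  expect_equal(p$subject_id, co@participants$subject_id)
  expect_equal(p$fsmc_total, co@participants$fsmc_total)
  ts <- readTimeseries(file.path(dir, "timeseries_S001.tsv"))
  expect_equal(ts, co@timeseries[["S001"]], tolerance = 1e-12)
  cov <- readCoverage(file.path(dir, "coverage.tsv"))
  expect_equal(unname(cov), unname(co@coverage))
  reg <- readRegionTable(file.path(dir, "regions.tsv"))
  expect_equal(reg$region_id, co@regions$region_id)
})

test_that("circuit sets round-trip through JSON", {
  d <- generateDensity(80, 5, 4, seed = 2)
  d2 <- d  # identical member set under a second map name
  cs <- buildCircuits(list(D2 = d, DAT = d2, NAT = generateDensity(80, 7, 4, seed = 3)),
                      names(d))
  f <- withr::local_tempfile(fileext = ".json")
  writeCircuits(cs, f)
  cs2 <- readCircuits(f)
  expect_equal(circuitMembers(cs2), circuitMembers(cs))
  expect_equal(mergedFrom(cs2), mergedFrom(cs))
})

test_that("planted switching rates are recovered from schedule ground truth", {
  # 20-subject cohort at the default 300-volume scan length; the window-domain label
  # matrix realized by each schedule is counted with the definitional
  # metrics and compared against the planted bookkeeping
  spec <- testCohortSpec(404, nVolumes = 300L)
  co <- generateCohort(spec, timeseries = FALSE)
  W <- 300 - 27 + 1

  # transition-domain truth: an event at transition t flips labels between
  # windows t and t + 1
  scheduleLabels <- function(sched, W) {
    base <- sched@baseAllegiance
    lab <- matrix(rep(base, W), nrow = length(base),
                  dimnames = list(names(base), NULL))
    ord <- order(vapply(sched@transitions, `[[`, numeric(1), "t"))
    for (ev in sched@transitions[ord])
      lab[ev$regions, (ev$t + 1):W] <- as.integer(ev$destination)
    lab
  }

  devRate <- numeric(0)
  for (id in names(co@schedules)) {
    sched <- co@schedules[[id]]
    lab <- scheduleLabels(sched, W)

    # every planted switch appears exactly once per region
    sw <- rowSums(lab[, -1, drop = FALSE] != lab[, -W, drop = FALSE])
    expect_identical(unname(sw), as.numeric(co@truth$nEvents[[id]]))

    # mode bookkeeping: classification can only upgrade a planted disjoint
    # switch to cohesive (two independent events coinciding in time and
    # destination), never the reverse
    modeCount <- c(cohesive = 0, disjoint = 0)
    for (ev in sched@transitions)
      modeCount[ev$mode] <- modeCount[ev$mode] + length(ev$regions)
    cls <- classifySwitches(lab)
    nCoh <- sum(cls == "cohesive"); nDis <- sum(cls == "disjoint")
    expect_equal(nCoh + nDis, sum(modeCount))
    expect_gte(nCoh, modeCount[["cohesive"]])
    expect_lte(nDis, modeCount[["disjoint"]])
    # coincidence upgrades stay rare
    expect_lte(nCoh - modeCount[["cohesive"]], 0.05 * sum(modeCount) + 3)

    devRate[id] <- sum(sw) / sum(co@truth$nEligible[[id]]) -
      co@truth$switchRate[[id]]
  }
  # pooled switch rate recovers the nominal planted rate within 3 MC SE
  expect_lt(abs(mean(devRate)), 3 * sd(devRate) / sqrt(length(devRate)))

  # cohesion + disjointedness decompose flexibility on truth matrices too
  lab1 <- scheduleLabels(co@schedules[[1]], W)
  cd <- cohesionDisjointedness(lab1)
  expect_equal(unname(cd$cohesion + cd$disjointedness),
               unname(flexibility(lab1)), tolerance = 1e-15)
})
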
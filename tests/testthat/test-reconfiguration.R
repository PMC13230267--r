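planOf <- function(nw, width = 27) makeWindows(nw + width - 1, width, 1)

amat <- function(lab, k = 8L) {
  new("AllegianceMatrix", labels = lab, kTotal = as.integer(k),
      plan = planOf(ncol(lab)))
}

test_that("flexibility counts switch fractions", {
  lab <- rbind(A = rep(1L, 10), B = rep(c(1L, 2L), 5))
  expect_equal(flexibility(lab), c(A = 0, B = 1))
  expect_error(flexibility(lab[, 1, drop = FALSE]), "at least 2")

  # uniform-random labels: expected flexibility 1 - 1/K
  set.seed(8)
  lab <- randomLabels(1000, 274, 8)
  f <- flexibility(lab)
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - (1 - 1 / 8)), 3 * se)
})

test_that("promiscuity is the visited fraction of all networks", {
  expect_equal(promiscuity(matrix(2L, 1, 10), 8), 0.125)
  expect_equal(promiscuity(matrix(1:8, 1, 8, byrow = TRUE), 8), 1)
  expect_equal(promiscuity(matrix(c(1:7, 7L), 1, 8), 8), 0.875)
  expect_error(promiscuity(matrix(9L, 1, 3), 8), "kTotal")
})

test_that("switch classification follows the shared-destination rule", {
  # three regions moving to network 4 at t = 5: all cohesive
  lab <- matrix(1L, 4, 8)
  lab[1:3, 6:8] <- 4L
  cls <- classifySwitches(lab)
  expect_equal(unname(cls[1:3, 5]), rep("cohesive", 3))
  expect_equal(unname(cls[4, 5]), "none")

  # a lone mover is disjoint
  solo <- matrix(1L, 3, 6)
  solo[2, 4:6] <- 3L
  expect_equal(unname(classifySwitches(solo)[2, 3]), "disjoint")

  # simultaneous switches to different destinations: both disjoint
  two <- matrix(1L, 2, 4)
  two[1, 3:4] <- 2L
  two[2, 3:4] <- 3L
  expect_equal(unname(classifySwitches(two)[, 2]), c("disjoint", "disjoint"))
})

test_that("cohesion and disjointedness decompose flexibility exactly", {
  # all regions always switching together
  lab <- matrix(rep(c(1L, 2L), 5), 3, 10, byrow = TRUE)
  cd <- cohesionDisjointedness(lab)
  expect_equal(cd$cohesion, flexibility(lab))
  expect_equal(cd$disjointedness, rep(0, 3))

  # single switching region: all disjoint
  solo <- matrix(1L, 3, 10)
  solo[1, ] <- rep(c(1L, 3L), 5)
  cds <- cohesionDisjointedness(solo)
  expect_equal(unname(cds$disjointedness[1]), unname(flexibility(solo)[1]))
  expect_equal(unname(cds$cohesion[1]), 0)
})

test_that("metrics match the brute-force oracle on random label matrices", {
  set.seed(123)
  for (i in 1:300) {
    nr <- sample(2:10, 1)
    nw <- sample(2:12, 1)
    k <- sample(2:8, 1)
    lab <- randomLabels(nr, nw, k)
    oracle <- bruteMetrics(lab, 8)
    cd <- cohesionDisjointedness(lab)
    expect_equal(unname(flexibility(lab)), oracle$flexibility)
    expect_equal(unname(promiscuity(lab, 8)), oracle$promiscuity)
    expect_equal(unname(cd$cohesion), oracle$cohesion)
    expect_equal(unname(cd$disjointedness), oracle$disjointedness)
    # decomposition: exact on counts, 1e-15 on fractions
    expect_equal(unname(cd$cohesion + cd$disjointedness),
                 unname(flexibility(lab)), tolerance = 1e-15)
  }
})

test_that("metrics are invariant under consistent relabeling", {
  set.seed(9)
  lab <- randomLabels(6, 12, 5)
  perm <- sample(8)
  relab <- matrix(perm[lab], nrow(lab), ncol(lab))
  expect_equal(unname(flexibility(relab)), unname(flexibility(lab)))
  expect_equal(unname(promiscuity(relab, 8)), unname(promiscuity(lab, 8)))
  cd <- cohesionDisjointedness(lab); cd2 <- cohesionDisjointedness(relab)
  expect_equal(unname(cd2$cohesion), unname(cd$cohesion))
  expect_equal(unname(cd2$disjointedness), unname(cd$disjointedness))
})

test_that("allegiance assignment recovers planted structure", {
  # no switches, noiseless: every window matches the base allegiance
  base <- setNames(rep(1:4, each = 3L), sprintf("R%02d", 1:12))
  sched <- switchSchedule(base, kTotal = 4L, windowWidth = 10L)
  ts <- generateTimeseries(sched, 60, noiseSd = 0, seed = 2)
  plan <- makeWindows(60, 10)
  al <- assignAllegiance(windowedZArray(ts, plan), base, plan, 4L)
  expect_true(all(allegianceLabels(al) == base))

  # planted cohesive event: exactly the named regions change, between the
  # flanking interior windows; the movers come from three different source
  # networks so every network keeps faithful members
  ev <- list(list(t = 10L, regions = c("R01", "R04", "R07"),
                  destination = 4L, mode = "cohesive"))
  sched2 <- switchSchedule(base, ev, kTotal = 4L, windowWidth = 10L)
  ts2 <- generateTimeseries(sched2, 60, noiseSd = 0, seed = 3)
  al2 <- assignAllegiance(windowedZArray(ts2, plan), base, plan, 4L)
  tru <- windowTruth(sched2, plan)
  lab2 <- allegianceLabels(al2)
  expect_true(all(lab2[!is.na(tru)] == tru[!is.na(tru)]))
  interior <- which(!is.na(tru[1, ]))
  sub <- lab2[, interior]
  cls <- classifySwitches(sub)
  swTrans <- which(apply(cls != "none", 2, any))
  expect_length(swTrans, 1)
  movers <- c("R01", "R04", "R07")
  expect_equal(unname(cls[movers, swTrans]), rep("cohesive", 3))
  expect_true(all(cls[setdiff(rownames(cls), movers), swTrans] == "none"))
})

test_that("allegiance ties keep the previous label deterministically", {
  # symmetric fixture: region X exactly equally connected to networks 1 and
  # 2 in every window
  v <- matrix(0, 5, 5,
              dimnames = list(c("X", "A1", "A2", "B1", "B2"),
                              c("X", "A1", "A2", "B1", "B2")))
  v["X", c("A1", "A2", "B1", "B2")] <- 0.5
  v[c("A1", "A2", "B1", "B2"), "X"] <- 0.5
  v["A1", "A2"] <- v["A2", "A1"] <- 2
  v["B1", "B2"] <- v["B2", "B1"] <- 2
  diag(v) <- NA
  arr <- array(v, dim = c(5, 5, 3), dimnames = list(rownames(v), rownames(v), NULL))
  codes <- c(X = 1L, A1 = 1L, A2 = 1L, B1 = 2L, B2 = 2L)
  plan <- makeWindows(5, 3, 1)
  a1 <- assignAllegiance(arr, codes, plan, 2L)
  a2 <- assignAllegiance(arr, codes, plan, 2L)
  expect_identical(allegianceLabels(a1), allegianceLabels(a2))
  # X's mean to network 1 (A1, A2, excluding self) equals network 2: tie,
  # first window takes the lowest label and later windows keep it
  expect_equal(unname(allegianceLabels(a1)["X", ]), rep(1L, 3))
})

test_that("single-member networks are rejected for their own member", {
  v <- matrix(0.5, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(v) <- NA
  arr <- array(v, dim = c(3, 3, 1), dimnames = dimnames(v)[c(1, 2)])
  plan <- makeWindows(3, 3)
  expect_error(
    assignAllegiance(array(v, c(3, 3, 1)), c(A = 1L, B = 1L, C = 2L),
                     plan, 2L),
    "single member")
})

test_that("aggregation averages circuits and the whole brain", {
  m <- data.frame(region_id = sprintf("R%d", 1:6),
                  flexibility = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  cs <- new("CircuitSet",
            circuits = list(one = "R1", left = sprintf("R%d", 1:3),
                            right = sprintf("R%d", 4:6)),
            mergedFrom = list(), provenance = list())
  agg <- aggregateReconfig(m, cs)
  expect_equal(agg$flexibility[agg$unit == "one"], 0.1)
  expect_equal(agg$flexibility[agg$unit == "global"], mean(m$flexibility))
  # two disjoint circuits covering all regions equally: global equals the
  # mean of the two circuit means
  expect_equal(agg$flexibility[agg$unit == "global"],
               mean(agg$flexibility[agg$unit %in% c("left", "right")]))
  expect_error(aggregateReconfig(m, cs, retainedRegions = sprintf("R%d", 1:5)),
               "outside the retained set")
})
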
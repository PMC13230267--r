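# Independent brute-force oracles, kept deliberately naive: they enumerate
# the definitions directly and share no code with the implementation.

# reconfiguration metrics by enumerating every (region, transition) pair
bruteMetrics <- function(lab, kTotal) {
  nr <- nrow(lab); nw <- ncol(lab)
  flex <- coh <- dis <- numeric(nr)
  prom <- numeric(nr)
  for (i in seq_len(nr)) {
    nSwitch <- nCoh <- nDis <- 0
    for (t in seq_len(nw - 1L)) {
      if (lab[i, t + 1L] == lab[i, t]) next
      nSwitch <- nSwitch + 1
      partner <- FALSE
      for (j in seq_len(nr)) {
        if (j == i) next
        if (lab[j, t + 1L] != lab[j, t] &&
            lab[j, t + 1L] == lab[i, t + 1L]) partner <- TRUE
      }
      if (partner) nCoh <- nCoh + 1 else nDis <- nDis + 1
    }
    flex[i] <- nSwitch / (nw - 1L)
    coh[i] <- nCoh / (nw - 1L)
    dis[i] <- nDis / (nw - 1L)
    prom[i] <- length(unique(lab[i, ])) / kTotal
  }
  list(flexibility = flex, promiscuity = prom, cohesion = coh,
       disjointedness = dis)
}

# Benjamini-Hochberg from its step-up definition
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# group F via explicit residual sums of squares of nested least-squares fits
ancovaOracleF <- function(y, group, covariates) {
  g <- as.factor(group)
  X0 <- stats::model.matrix(~ sex + age + education, data = covariates)
  X1 <- cbind(X0, stats::model.matrix(~ g)[, -1, drop = FALSE])
  rss <- function(X) {
    beta <- qr.solve(qr(X), y)
    sum((y - X %*% beta)^2)
  }
  rss0 <- rss(X0); rss1 <- rss(X1)
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - ncol(X1)
  Fval <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(F = Fval, p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

randomLabels <- function(nr, nw, k) {
  matrix(sample.int(k, nr * nw, replace = TRUE), nr, nw,
         dimnames = list(sprintf("R%02d", seq_len(nr)), NULL))
}

# small cohort used by several tests: 80 regions keep every network's
# latent well represented even under cohesive co-visits
testCohortSpec <- function(seed, nPerGroup = c(HC = 5L, none = 5L,
                                               `mild/moderate` = 5L,
                                               severe = 5L),
                           nRegions = 80L, nVolumes = 100L, ...) {
  cohortSpec(nPerGroup = nPerGroup, nRegions = nRegions,
             nVolumes = nVolumes, seed = as.integer(seed), ...)
}

rsnCodesOf <- function(cohort) {
  lv <- unique(c(setdiff(cohort@regions$rsn_label, "DGM"), "DGM"))
  regionRSNCodes(cohort@regions, lv)
}
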
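#' Assign window-wise network allegiance
#'
#' For each window and region, the allegiance is the network whose member
#' regions (excluding the region itself) have the highest mean windowed
#' connectivity with that region. Ties are broken deterministically: the
#' previous window's label is kept when it is among the tied maxima,
#' otherwise the lowest network index wins (lowest index also in the first
#' window).
#'
#' @param windowed windowed connectivity: either the list of
#'   [FCMatrix-class] objects from [windowedFC()] or the 3-D array from
#'   [windowedZArray()]
#' @param regionRSN named integer vector mapping region id to network label
#'   1..K, in the row order of the connectivity matrices
#' @param plan the [WindowPlan-class] that produced the windows
#' @param kTotal total number of networks K (default 8)
#' @return An [AllegianceMatrix-class].
#' @export
assignAllegiance <- function(windowed, regionRSN, plan, kTotal = 8L) {
  kTotal <- as.integer(kTotal)
  if (is.list(windowed)) {
    arr <- array(NA_real_, dim = c(dim(windowed[[1]]@values),
                                   length(windowed)))
    dimnames(arr) <- c(dimnames(windowed[[1]]@values), list(NULL))
    for (w in seq_along(windowed)) arr[, , w] <- windowed[[w]]@values
    windowed <- arr
  }
  nr <- dim(windowed)[1]
  nw <- dim(windowed)[3]
  if (length(regionRSN) != nr)
    stop("regionRSN length (", length(regionRSN),
         ") does not match number of regions (", nr, ")")
  rsn <- as.integer(regionRSN)
  if (any(rsn < 1L | rsn > kTotal)) stop("network labels must lie in 1..K")

  # membership matrix and per-(region, network) denominator excluding self
  M <- matrix(0, nr, kTotal)
  M[cbind(seq_len(nr), rsn)] <- 1
  sizes <- colSums(M)
  denom <- matrix(rep(sizes, each = nr), nr, kTotal) -
    M  # own network loses the region itself
  own_single <- denom[cbind(seq_len(nr), rsn)] == 0
  if (any(own_single)) {
    bad <- names(regionRSN)[own_single]
    if (is.null(bad)) bad <- which(own_single)
    stop("network with a single member cannot host its own region: ",
         paste(bad, collapse = ", "))
  }

  labels <- matrix(NA_integer_, nr, nw,
                   dimnames = list(names(regionRSN), NULL))
  prev <- rep(NA_integer_, nr)
  for (w in seq_len(nw)) {
    Z <- windowed[, , w]
    diag(Z) <- 0
    means <- (Z %*% M) / denom
    means[denom == 0] <- -Inf  # network with no other members: unassignable
    mx <- matrixStats_rowMax(means)
    cur <- integer(nr)
    for (i in seq_len(nr)) {
      tied <- which(means[i, ] >= mx[i] - 1e-12)
      cur[i] <- if (!is.na(prev[i]) && prev[i] %in% tied) prev[i]
                else tied[1L]
    }
    labels[, w] <- cur
    prev <- cur
  }
  new("AllegianceMatrix", labels = labels, kTotal = kTotal, plan = plan)
}

# rowwise max without extra deps
matrixStats_rowMax <- function(m) {
  apply(m, 1L, max)
}

#' Run the windowed pipeline for one subject
#'
#' Convenience wrapper: window plan, windowed |z| connectivity, allegiance
#' assignment, and the four region-level reconfiguration metrics.
#'
#' @param ts region-by-volume matrix with region ids as rownames
#' @param regionRSN named integer vector of network labels 1..K
#' @param width,step window geometry (defaults 27 and 1)
#' @param kTotal number of networks
#' @return A list with elements \code{plan}, \code{allegiance}
#'   ([AllegianceMatrix-class]) and \code{metrics} (data.frame with one row
#'   per region: flexibility, promiscuity, cohesion, disjointedness).
#' @export
reconfigureSubject <- function(ts, regionRSN, width = 27L, step = 1L,
                               kTotal = 8L) {
  plan <- makeWindows(ncol(ts), width, step)
  arr <- windowedZArray(ts, plan)
  alleg <- assignAllegiance(arr, regionRSN, plan, kTotal)
  cd <- cohesionDisjointedness(alleg)
  metrics <- data.frame(
    region_id = rownames(allegianceLabels(alleg)),
    flexibility = flexibility(alleg),
    promiscuity = promiscuity(alleg, kTotal),
    cohesion = cd$cohesion,
    disjointedness = cd$disjointedness,
    row.names = NULL
  )
  list(plan = plan, allegiance = alleg, metrics = metrics)
}
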
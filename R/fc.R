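.CLIP <- 1 - 1e-7

# Pearson -> clipped Fisher z -> absolute value, on a region x volume matrix.
# Returns region x region matrix with NA diagonal.
.absZ <- function(ts, context = "time series") {
  sds <- apply(ts, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance region in ", context, ": ",
         paste(bad, collapse = ", "))
  }
  r <- stats::cor(t(ts))
  r <- sign(r) * pmin(abs(r), .CLIP)
  z <- abs(atanh(r))
  diag(z) <- NA_real_
  z
}

#' Static functional connectivity
#'
#' Pearson correlation between all region pairs over the full time series,
#' followed by the static transform chain: Fisher r-to-z (with |r| clipped to
#' 1 - 1e-7 so saturated correlations stay finite), absolute value, and
#' division by the off-diagonal maximum. The result has all off-diagonal
#' values in [0, 1] with maximum exactly 1.
#'
#' @param ts numeric matrix, regions in rows, volumes in columns; rownames
#'   are region ids
#' @return An [FCMatrix-class] of kind "static".
#' @seealso [windowedFC()], [withinCircuitFC()]
#' @export
staticFC <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3L) stop("need at least 3 volumes")
  z <- .absZ(ts, "static FC input")
  mx <- max(z, na.rm = TRUE)
  if (mx == 0) stop("all correlations are zero; cannot max-normalize")
  new("FCMatrix", values = z / mx, kind = "static",
      transformLog = c("pearson", "fisher_z(clip=1e-07)", "abs",
                       "max_normalize"))
}

#' Windowed functional connectivity
#'
#' Per window of the plan: Pearson correlation, clipped Fisher r-to-z,
#' absolute value. Windowed matrices are not max-normalized; the downstream
#' allegiance argmax is invariant to a global positive rescaling.
#'
#' @param ts numeric matrix, regions in rows, volumes in columns
#' @param plan a [WindowPlan-class] over \code{ncol(ts)} volumes
#' @return A list of [FCMatrix-class] objects of kind "windowed", one per
#'   window.
#' @export
windowedFC <- function(ts, plan) {
  arr <- windowedZArray(ts, plan)
  lapply(seq_len(dim(arr)[3]), function(w) {
    new("FCMatrix", values = arr[, , w], kind = "windowed",
        transformLog = c("pearson", "fisher_z(clip=1e-07)", "abs"))
  })
}

#' Windowed |z| connectivity as a 3-D array
#'
#' Fast path behind [windowedFC()]: the same per-window transform chain,
#' returned as a regions x regions x windows array (NA diagonals). Used by
#' the subject-level pipeline where allocating one S4 object per window
#' would dominate runtime.
#'
#' @inheritParams windowedFC
#' @return numeric array of dimension (regions, regions, windows)
#' @export
windowedZArray <- function(ts, plan) {
  ts <- as.matrix(ts)
  stopifnot(is(plan, "WindowPlan"))
  if (plan@nVolumes != ncol(ts))
    stop("plan covers ", plan@nVolumes, " volumes but series has ", ncol(ts))
  nw <- nWindows(plan)
  r <- nrow(ts)
  out <- array(NA_real_, dim = c(r, r, nw),
               dimnames = list(rownames(ts), rownames(ts), NULL))
  for (w in seq_len(nw)) {
    out[, , w] <- .absZ(ts[, .windowIndices(plan, w), drop = FALSE],
                        sprintf("window %d", w))
  }
  out
}

#' Mean within-circuit static connectivity
#'
#' Mean of the FC values over all unordered pairs of circuit member regions
#' (each pair counted once, diagonal excluded).
#'
#' @param fc an [FCMatrix-class] (or plain symmetric matrix with region
#'   dimnames)
#' @param circuit character vector of region ids with at least two members
#'   present in \code{fc}
#' @return A single numeric value.
#' @export
withinCircuitFC <- function(fc, circuit) {
  v <- if (is(fc, "FCMatrix")) fc@values else as.matrix(fc)
  present <- intersect(circuit, rownames(v))
  if (length(present) < 2L)
    stop("circuit has fewer than 2 regions present in the FC matrix")
  sub <- v[present, present]
  mean(sub[upper.tri(sub)])
}
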
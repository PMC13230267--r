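#' Build a sliding-window plan
#'
#' Splits a time series of \code{nVolumes} volumes into overlapping
#' rectangular windows of \code{width} volumes at stride \code{step}. With
#' the defaults used throughout (width 27, step 1), 300 volumes yield 274
#' windows.
#'
#' @param nVolumes number of volumes in the series
#' @param width window width in volumes (default 27)
#' @param step stride between window starts (default 1)
#' @return A [WindowPlan-class].
#' @examples
#' nWindows(makeWindows(300))  # 274
#' @export
makeWindows <- function(nVolumes, width = 27L, step = 1L) {
  nVolumes <- as.integer(nVolumes)
  width <- as.integer(width)
  step <- as.integer(step)
  if (width > nVolumes)
    stop("width (", width, ") exceeds nVolumes (", nVolumes, ")")
  if (step < 1L) stop("step must be at least 1")
  n <- (nVolumes - width) %/% step + 1L
  new("WindowPlan", nVolumes = nVolumes, width = width, step = step,
      starts = seq.int(1L, by = step, length.out = n))
}

# volume indices covered by window w (1-based inclusive)
.windowIndices <- function(plan, w) {
  s <- plan@starts[w]
  seq.int(s, s + plan@width - 1L)
}
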
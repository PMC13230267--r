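#' Accessors for circuitDyn classes
#'
#' Small accessor generics: window geometry (\code{nWindows},
#' \code{windowWidth}, \code{windowStep}, \code{windowStarts}), FC matrix
#' content (\code{fcValues}, \code{fcKind}, \code{transformLog}), allegiance
#' labels (\code{allegianceLabels}, \code{kTotal}) and circuit content
#' (\code{circuitNames}, \code{circuitMembers}, \code{mergedFrom}).
#'
#' @param x an object of the documented class
#' @param name for \code{circuitMembers}, a circuit name; omit for all
#' @return The extracted component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setGeneric("windowWidth", function(x) standardGeneric("windowWidth"))
#' @rdname accessors
#' @export
setGeneric("windowStep", function(x) standardGeneric("windowStep"))
#' @rdname accessors
#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))
#' @rdname accessors
#' @export
setGeneric("fcValues", function(x) standardGeneric("fcValues"))
#' @rdname accessors
#' @export
setGeneric("fcKind", function(x) standardGeneric("fcKind"))
#' @rdname accessors
#' @export
setGeneric("transformLog", function(x) standardGeneric("transformLog"))
#' @rdname accessors
#' @export
setGeneric("allegianceLabels", function(x) standardGeneric("allegianceLabels"))
#' @rdname accessors
#' @export
setGeneric("kTotal", function(x) standardGeneric("kTotal"))
#' @rdname accessors
#' @export
setGeneric("circuitNames", function(x) standardGeneric("circuitNames"))
#' @rdname accessors
#' @export
setGeneric("circuitMembers", function(x, name) standardGeneric("circuitMembers"))
#' @rdname accessors
#' @export
setGeneric("mergedFrom", function(x) standardGeneric("mergedFrom"))

#' @rdname accessors
#' @export
setMethod("nWindows", "WindowPlan", function(x) length(x@starts))
#' @rdname accessors
#' @export
setMethod("windowWidth", "WindowPlan", function(x) x@width)
#' @rdname accessors
#' @export
setMethod("windowStep", "WindowPlan", function(x) x@step)
#' @rdname accessors
#' @export
setMethod("windowStarts", "WindowPlan", function(x) x@starts)

#' @rdname accessors
#' @export
setMethod("fcValues", "FCMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("fcKind", "FCMatrix", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("transformLog", "FCMatrix", function(x) x@transformLog)

#' @rdname accessors
#' @export
setMethod("allegianceLabels", "AllegianceMatrix", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("kTotal", "AllegianceMatrix", function(x) x@kTotal)
#' @rdname accessors
#' @export
setMethod("nWindows", "AllegianceMatrix", function(x) ncol(x@labels))

#' @rdname accessors
#' @export
setMethod("circuitNames", "CircuitSet", function(x) names(x@circuits))
#' @rdname accessors
#' @export
setMethod("circuitMembers", "CircuitSet", function(x, name) {
  if (missing(name)) return(x@circuits)
  if (!name %in% names(x@circuits))
    stop("unknown circuit: ", name)
  x@circuits[[name]]
})
#' @rdname accessors
#' @export
setMethod("mergedFrom", "CircuitSet", function(x) x@mergedFrom)

setMethod("show", "WindowPlan", function(object) {
  cat(sprintf("WindowPlan: %d windows of width %d (step %d) over %d volumes\n",
              nWindows(object), object@width, object@step, object@nVolumes))
})

setMethod("show", "FCMatrix", function(object) {
  cat(sprintf("FCMatrix (%s): %d x %d regions\n  transforms: %s\n",
              object@kind, nrow(object@values), ncol(object@values),
              paste(object@transformLog, collapse = " -> ")))
})

setMethod("show", "AllegianceMatrix", function(object) {
  cat(sprintf("AllegianceMatrix: %d regions x %d windows, K = %d networks\n",
              nrow(object@labels), ncol(object@labels), object@kTotal))
})

setMethod("show", "CircuitSet", function(object) {
  cat(sprintf("CircuitSet of %d circuit(s):\n", length(object@circuits)))
  for (nm in names(object@circuits)) {
    prov <- object@provenance[[nm]]
    how <- if (is.null(prov)) "" else sprintf(" [%s]", prov$method)
    cat(sprintf("  %s: %d regions%s\n", nm, length(object@circuits[[nm]]), how))
  }
})

setMethod("show", "SwitchSchedule", function(object) {
  cat(sprintf("SwitchSchedule: %d regions, K = %d, %d planted event(s), width %d\n",
              length(object@baseAllegiance), object@kTotal,
              length(object@transitions), object@windowWidth))
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:\n")
  cat("  groups: ", paste(sprintf("%s=%d", names(object@nPerGroup),
                                  object@nPerGroup), collapse = ", "), "\n")
  cat(sprintf("  %d regions x %d volumes, K = %d, window width %d\n",
              object@nRegions, object@nVolumes, object@nRSN,
              object@windowWidth))
  cat("  switch rates: ", paste(sprintf("%s=%.3f", names(object@switchRate),
                                        object@switchRate), collapse = ", "),
      "\n")
  cat(sprintf("  noise sd %.3f, cohesive fraction %.2f, seed %d\n",
              object@noiseSd, object@cohesiveFraction, object@seed))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d subjects, %d regions, %d volumes, %d time-series matrices\n",
              nrow(object@participants), object@spec@nRegions,
              object@spec@nVolumes, length(object@timeseries)))
})
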
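.fsmcCutoffs <- list(
  total = c(mild = 43, moderate = 53, severe = 63),
  cognitive = c(mild = 22, moderate = 28, severe = 34),
  motor = c(mild = 22, moderate = 27, severe = 32)
)

#' Classify fatigue severity from an FSMC score
#'
#' Four-level classification by the published cut-offs, all inclusive
#' ("scores of at least ..."): total 43/53/63, cognitive 22/28/34, motor
#' 22/27/32. \code{fatigueGroup()} returns the three-level analysis grouping
#' that merges mild and moderate.
#'
#' @param score FSMC scale score(s)
#' @param scheme one of "total", "cognitive", "motor"
#' @return \code{classifyFatigue}: character vector with levels "none",
#'   "mild", "moderate", "severe". \code{fatigueGroup}: levels "none",
#'   "mild/moderate", "severe".
#' @examples
#' classifyFatigue(74, "total")   # "severe"
#' classifyFatigue(29, "total")   # "none"
#' fatigueGroup(31, "motor")      # "mild/moderate"
#' @export
classifyFatigue <- function(score, scheme = c("total", "cognitive",
                                              "motor")) {
  scheme <- match.arg(scheme)
  if (any(score < 0 | score > 100, na.rm = TRUE))
    stop("FSMC scores must lie in [0, 100]")
  cut <- .fsmcCutoffs[[scheme]]
  out <- rep("none", length(score))
  out[score >= cut["mild"]] <- "mild"
  out[score >= cut["moderate"]] <- "moderate"
  out[score >= cut["severe"]] <- "severe"
  out[is.na(score)] <- NA_character_
  out
}

#' @rdname classifyFatigue
#' @export
fatigueGroup <- function(score, scheme = c("total", "cognitive", "motor")) {
  four <- classifyFatigue(score, scheme)
  ifelse(four %in% c("mild", "moderate"), "mild/moderate", four)
}

.schemeColumn <- function(scheme) {
  paste0("fsmc_", match.arg(scheme, c("total", "cognitive", "motor")))
}

#' Screen participants on depression and control fatigue
#'
#' Drops any record with HADS-D of 11 or more (clinically relevant
#' depression), any healthy control reporting at least mild fatigue
#' (FSMC total of 43 or more), and any record with missing required scores;
#' every exclusion is logged with its reason.
#'
#' @param records participant data.frame with columns \code{subject_id},
#'   \code{group} (HC or pwMS), \code{fsmc_total}, \code{hads_d}
#' @return list with \code{retained} (data.frame) and \code{exclusions}
#'   (data.frame subject_id, reason).
#' @export
screenParticipants <- function(records) {
  need <- c("subject_id", "group", "fsmc_total", "hads_d")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("participant table lacks columns: ", paste(miss, collapse = ", "))
  incomplete <- is.na(records$fsmc_total) | is.na(records$hads_d)
  depressed <- !incomplete & records$hads_d >= 11
  fatiguedHC <- !incomplete & !depressed &
    records$group == "HC" & records$fsmc_total >= 43
  reason <- rep(NA_character_, nrow(records))
  reason[incomplete] <- "missing FSMC or HADS score"
  reason[depressed] <- "HADS-D >= 11"
  reason[fatiguedHC] <- "healthy control with FSMC total >= 43"
  drop <- !is.na(reason)
  list(
    retained = records[!drop, , drop = FALSE],
    exclusions = data.frame(subject_id = records$subject_id[drop],
                            reason = reason[drop])
  )
}

# round half-up to `digits` decimals (presentation rounding for group
# percentages; base round() is round-half-even)
.roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Group counts and percentages for people with MS
#'
#' Classifies retained people with MS under the given FSMC scheme and
#' tabulates counts with percentages of the total pwMS sample, rounded
#' half-up to one decimal (87 of 217 gives 40.1).
#'
#' @param records screened participant data.frame
#' @param scheme FSMC scheme ("total", "cognitive" or "motor")
#' @return data.frame with columns \code{group}, \code{n}, \code{percent};
#'   attribute \code{nTotal} holds the pwMS denominator.
#' @export
groupTable <- function(records, scheme = "total") {
  if (nrow(records) == 0L) stop("empty participant table")
  col <- .schemeColumn(scheme)
  if (!col %in% names(records)) stop("missing column: ", col)
  pw <- records[records$group != "HC", , drop = FALSE]
  if (nrow(pw) == 0L) stop("no pwMS records to tabulate")
  lab <- fatigueGroup(pw[[col]], scheme)
  lv <- c("none", "mild/moderate", "severe")
  n <- vapply(lv, function(g) sum(lab == g), integer(1))
  out <- data.frame(group = lv, n = unname(n),
                    percent = .roundHalfUp(100 * unname(n) / nrow(pw)))
  attr(out, "nTotal") <- nrow(pw)
  out
}

#' Restrict to relapsing-remitting MS (plus controls)
#'
#' Sensitivity-analysis subset: keeps all healthy controls and the people
#' with MS whose phenotype is relapsing-remitting.
#'
#' @param records participant data.frame with columns \code{group} and
#'   \code{ms_type} (RRMS/PMS/CIS, NA for HC)
#' @return The filtered data.frame.
#' @export
subsetRRMS <- function(records) {
  if (!"ms_type" %in% names(records))
    stop("participant table lacks the ms_type column")
  keep <- records$group == "HC" |
    (!is.na(records$ms_type) & records$ms_type == "RRMS")
  records[keep, , drop = FALSE]
}
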
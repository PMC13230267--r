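#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Least-squares fit of the outcome on sex, age and years of education
#' followed by the group factor (model column order: intercept, covariates,
#' group). The group F statistic comes from the sequential sum of squares
#' for the group block, i.e. the group effect adjusted for the covariates.
#' Pairwise contrasts are t-tests on adjusted (covariates held at their
#' means) group-mean differences using the full-model residual variance,
#' uncorrected across the group pairs.
#'
#' @param outcome numeric vector of per-subject values
#' @param group factor or character vector of group labels (at least two
#'   groups with two or more subjects each)
#' @param covariates data.frame with columns \code{sex} (two-level) and
#'   numeric \code{age} and \code{education}
#' @return list with elements \code{F}, \code{df} (between, residual),
#'   \code{p}, \code{covariateP} (named, sequential), \code{adjustedMeans},
#'   \code{contrasts} (data.frame: pair, estimate, t, p) and \code{n}.
#' @export
runAncova <- function(outcome, group, covariates) {
  need <- c("sex", "age", "education")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop("covariates lack columns: ", paste(miss, collapse = ", "))
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs at least 2 subjects")
  df <- data.frame(y = outcome,
                   sex = as.factor(covariates$sex),
                   age = as.numeric(covariates$age),
                   education = as.numeric(covariates$education),
                   group = group)
  fit <- stats::lm(y ~ sex + age + education + group, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("singular design; aliased column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  an <- stats::anova(fit)  # sequential (covariates first, group last)
  gRow <- match("group", rownames(an))
  covP <- stats::setNames(an[need, "Pr(>F)"], need)

  # adjusted means: covariates at sample means, per-group effects added
  V <- stats::vcov(fit)
  sexNum <- as.numeric(df$sex) - 1
  base <- cf["(Intercept)"] + mean(sexNum) * cf[2L] +
    mean(df$age) * cf["age"] + mean(df$education) * cf["education"]
  lv <- levels(group)
  gCoef <- c(0, cf[paste0("group", lv[-1L])])
  names(gCoef) <- lv
  adjustedMeans <- base + gCoef

  pairs <- utils::combn(lv, 2L)
  dfRes <- an["Residuals", "Df"]
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    L <- stats::setNames(rep(0, length(cf)), names(cf))
    if (a != lv[1L]) L[paste0("group", a)] <- 1
    if (b != lv[1L]) L[paste0("group", b)] <- -1
    est <- sum(L * cf)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tval <- est / se
    data.frame(pair = paste(a, "vs", b), estimate = est, t = tval,
               p = 2 * stats::pt(-abs(tval), dfRes))
  }))
  rownames(contrasts) <- NULL
  list(F = an[gRow, "F value"],
       df = c(between = an[gRow, "Df"], residual = dfRes),
       p = an[gRow, "Pr(>F)"],
       covariateP = covP,
       adjustedMeans = adjustedMeans,
       contrasts = contrasts,
       n = nrow(df))
}

#' Benjamini-Hochberg adjustment within one family
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, applied to one outcome family at a time.
#'
#' @param p numeric vector of p values in [0, 1]
#' @return Adjusted p values in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Default analysis plan
#'
#' Outcome families mirror the result-table blocks: one static-FC family
#' across circuits, one flexibility family (global plus circuits), one
#' promiscuity family, and an optional volumes family. Cohesion and
#' disjointedness are gated: they are analyzed only for units whose
#' BH-adjusted flexibility group effect is significant at \code{alpha}.
#'
#' @param alpha significance level for the gate and contrast reporting
#' @return list with elements \code{alpha} and \code{gateOn}.
#' @export
defaultPlan <- function(alpha = 0.05) {
  list(alpha = alpha, gateOn = "flexibility")
}

#' Run the full group-comparison plan
#'
#' For each outcome family (static FC per circuit; flexibility and
#' promiscuity for global plus each circuit; volumes when provided): an
#' ANCOVA per outcome with Benjamini-Hochberg correction within the family.
#' Cohesion and disjointedness are then analyzed post hoc, only for the
#' units whose adjusted flexibility effect is significant at
#' \code{plan$alpha}; when no unit passes the gate, no cohesion or
#' disjointedness rows appear.
#'
#' @param metrics data.frame of reconfiguration metrics, long format:
#'   \code{subject_id}, \code{unit} ("global" or a circuit name), and
#'   columns \code{flexibility}, \code{promiscuity}, \code{cohesion},
#'   \code{disjointedness}
#' @param staticFC optional data.frame \code{subject_id}, \code{unit},
#'   \code{fc}
#' @param volumes optional data.frame \code{subject_id}, \code{unit},
#'   \code{volume}
#' @param participants data.frame with \code{subject_id}, \code{sex},
#'   \code{age}, \code{education_years} and the grouping column
#' @param groupColumn name of the group label column (default "fatigue_group")
#' @param plan list from [defaultPlan()]
#' @return list with \code{results} (one row per outcome: family, unit, F,
#'   df, p, p_adj, post_hoc flag) and \code{contrasts} (per pair).
#' @export
runPlan <- function(metrics, participants, staticFC = NULL, volumes = NULL,
                    groupColumn = "fatigue_group", plan = defaultPlan()) {
  need <- c("subject_id", "sex", "age", "education_years", groupColumn)
  miss <- setdiff(need, names(participants))
  if (length(miss))
    stop("participants table lacks columns: ", paste(miss, collapse = ", "))
  getOutcomes <- function(tab, col) {
    if (!col %in% names(tab)) stop("missing outcome column: ", col)
    units <- unique(tab$unit)
    out <- list()
    for (u in units) {
      sub <- tab[tab$unit == u, c("subject_id", col)]
      m <- merge(participants, sub, by = "subject_id")
      out[[u]] <- list(y = m[[col]], g = m[[groupColumn]],
                       cov = data.frame(sex = m$sex, age = m$age,
                                        education = m$education_years))
    }
    out
  }
  runFamSafe <- function(family, tab, col) {
    oc <- getOutcomes(tab, col)
    rows <- list(); contrasts <- list()
    for (u in names(oc)) {
      res <- runAncova(oc[[u]]$y, oc[[u]]$g, oc[[u]]$cov)
      rows[[u]] <- data.frame(family = family, unit = u, F = res$F,
                              df1 = res$df[["between"]],
                              df2 = res$df[["residual"]],
                              p = res$p, p_adj = NA_real_)
      cc <- res$contrasts
      cc$family <- family; cc$unit <- u
      contrasts[[u]] <- cc
    }
    tabOut <- do.call(rbind, rows)
    tabOut$p_adj <- bhAdjust(tabOut$p)
    rownames(tabOut) <- NULL
    list(table = tabOut, contrasts = do.call(rbind, contrasts))
  }

  fams <- list()
  if (!is.null(volumes))
    fams$volumes <- runFamSafe("volumes", volumes, "volume")
  if (!is.null(staticFC))
    fams$static_fc <- runFamSafe("static_fc", staticFC, "fc")
  fams$flexibility <- runFamSafe("flexibility", metrics, "flexibility")
  fams$promiscuity <- runFamSafe("promiscuity", metrics, "promiscuity")

  flex <- fams$flexibility$table
  gateUnits <- flex$unit[flex$p_adj < plan$alpha]
  if (length(gateUnits)) {
    sub <- metrics[metrics$unit %in% gateUnits, , drop = FALSE]
    fams$cohesion <- runFamSafe("cohesion", sub, "cohesion")
    fams$disjointedness <- runFamSafe("disjointedness", sub,
                                      "disjointedness")
  }
  results <- do.call(rbind, lapply(fams, `[[`, "table"))
  results$post_hoc <- results$family %in% c("cohesion", "disjointedness")
  rownames(results) <- NULL
  contrasts <- do.call(rbind, lapply(fams, `[[`, "contrasts"))
  rownames(contrasts) <- NULL
  list(results = results,
       contrasts = contrasts[, c("family", "unit", "pair", "estimate",
                                 "t", "p")],
       gateUnits = gateUnits)
}
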
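## Survival stage: two-group log-rank test (computed from first
## principles; tests cross-check against survival::survdiff), maximally
## selected rank-statistic cutpoint, Cox proportional hazards (via
## survival::coxph), and a per-feature screen.

## Observed events, summed expectations and hypergeometric variance for
## the indicated group over the pooled event-time grid (ties handled by
## summed expectations).
.logrankOEV <- function(time, event, inGroup) {
  eventTimes <- sort(unique(time[event == 1]))
  O <- sum(event[inGroup])
  E <- 0; V <- 0
  for (t in eventTimes) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & inGroup)
    d <- sum(event == 1 & time == t)
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V)
}

#' Two-group log-rank test
#'
#' Standard two-sided log-rank chi-square on the pooled event-time grid,
#' with tied event times handled by summed expectations. The statistic is
#' `(O - E)^2 / V` for either group; the p-value comes from chi-square
#' with 1 degree of freedom. A group without events triggers a warning
#' but the statistic is still computed.
#'
#' @param groups vector with exactly two distinct labels, one per patient
#' @param surv data.frame with columns `time` (> 0) and `event` (0/1)
#' @return list with `statistic`, `p`, `observed`, `expected`, `variance`
#'   (the latter three for the second group level)
#' @export
logrankTest <- function(groups, surv) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (length(groups) != nrow(surv))
    stop("groups must align with the survival table")
  .checkSurvTable(surv)
  for (g in levels(groups))
    if (sum(surv$event[groups == g]) == 0)
      warning("group '", g, "' has zero events")
  oev <- .logrankOEV(surv$time, surv$event, groups == levels(groups)[2])
  stat <- if (oev$V > 0) (oev$O - oev$E)^2 / oev$V else 0
  list(statistic = stat,
       p = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = oev$O, expected = oev$E, variance = oev$V)
}

.checkSurvTable <- function(surv) {
  if (!all(c("time", "event") %in% names(surv)))
    stop("survival table needs 'time' and 'event' columns")
  if (any(surv$time <= 0)) stop("times must be positive")
  if (!all(surv$event %in% c(0, 1))) stop("events must be 0/1")
  invisible(surv)
}

#' Maximally selected rank-statistic cutpoint
#'
#' Evaluates the standardized log-rank statistic `|O - E| / sqrt(V)` at
#' every candidate cutpoint of the continuous score between its `minProp`
#' and `1 - minProp` quantiles (high group: score > cutpoint; both groups
#' at least `minGroup`) and returns the maximizer. The log-rank p-value
#' reported at the selected cutpoint ignores the search and is therefore
#' inflated; the result carries a permanent `pInflated` flag. The Cox
#' hazard ratio of the dichotomy is estimated alongside.
#'
#' @param surv data.frame with columns `time`, `event`, `score`
#' @param minProp quantile band half-width for candidate cutpoints
#' @param minGroup minimal size of either score group
#' @return a [CutpointResult-class]
#' @export
maxstatCutpoint <- function(surv, minProp = 0.1, minGroup = 5) {
  .checkSurvTable(surv)
  if (!"score" %in% names(surv)) stop("survival table needs a 'score' column")
  if (nrow(surv) < 20) stop("need at least 20 patients")
  if (sum(surv$event) < 5) stop("need at least 5 events")
  score <- surv$score
  if (length(unique(score)) < 2) stop("all scores are identical")

  lo <- quantile(score, minProp)
  hi <- quantile(score, 1 - minProp)
  cand <- sort(unique(score))
  cand <- cand[cand >= lo & cand <= hi & cand < max(score)]
  sizes <- vapply(cand, function(cv) min(sum(score > cv), sum(score <= cv)),
                  numeric(1))
  cand <- cand[sizes >= minGroup]
  if (!length(cand))
    stop("no candidate cutpoint satisfies the quantile band and group size")

  z <- vapply(cand, function(cv) {
    oev <- .logrankOEV(surv$time, surv$event, score > cv)
    if (oev$V > 0) abs(oev$O - oev$E) / sqrt(oev$V) else 0
  }, numeric(1))
  best <- which.max(z)
  cut <- cand[best]
  high <- score > cut

  lrP <- pchisq(z[best]^2, df = 1, lower.tail = FALSE)
  cox <- coxHR(as.integer(high), surv)
  new("CutpointResult",
      cutpoint = unname(cut), statistic = unname(z[best]),
      groupSizes = c(sum(!high), sum(high)),
      logrankP = lrP, pInflated = TRUE,
      hr = cox$hr, ciLower = cox$ciLower, ciUpper = cox$ciUpper,
      coxP = cox$p)
}

#' Univariate Cox proportional-hazards hazard ratio
#'
#' Partial-likelihood fit (Newton iterations, Efron tie handling) of a
#' single covariate via the survival package, returning the hazard ratio
#' with Wald 95 percent confidence interval and p-value.
#'
#' @param covariate numeric score or two-level group per patient
#' @param surv data.frame with columns `time`, `event`
#' @param minEvents minimal number of events required
#' @return list with `hr`, `ciLower`, `ciUpper`, `p`, `coef`, `se`
#' @export
coxHR <- function(covariate, surv, minEvents = 10) {
  .checkSurvTable(surv)
  if (sum(surv$event) < minEvents)
    stop("need at least ", minEvents, " events")
  x <- if (is.factor(covariate) || is.character(covariate))
    as.integer(as.factor(covariate)) - 1L else as.numeric(covariate)
  if (length(x) != nrow(surv))
    stop("covariate must align with the survival table")
  fit <- withCallingHandlers(
    coxph(Surv(surv$time, surv$event) ~ x, ties = "efron",
          control = coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|Ran out of iterations", conditionMessage(w)))
        stop("Cox fit failed (possible complete separation or ",
             "non-convergence): ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 20)
    stop("Cox coefficient diverged; complete separation suspected")
  list(hr = exp(beta),
       ciLower = exp(beta - 1.96 * se),
       ciUpper = exp(beta + 1.96 * se),
       p = 2 * pnorm(-abs(beta / se)),
       coef = beta, se = se, fit = fit)
}

#' Screen features for survival association via maxstat + Cox
#'
#' For each feature (subcluster abundance or signature score per patient),
#' finds the maxstat cutpoint, dichotomizes, and estimates the Cox hazard
#' ratio of the high group; flags significance at Cox p < `alpha`.
#' Features failing the maxstat preconditions are flagged, not fatal.
#' The output is ordered by hazard ratio, failures last.
#'
#' @param features patients x features numeric matrix or data.frame
#' @param surv data.frame with columns `time`, `event`
#' @param alpha significance level for the flag
#' @param minProp,minGroup passed to [maxstatCutpoint()]
#' @return data.frame per feature: feature, cutpoint, statistic, hr,
#'   ciLower, ciUpper, coxP, logrankP, significant, failed
#' @export
survivalScreen <- function(features, surv, alpha = 0.05,
                           minProp = 0.1, minGroup = 5) {
  features <- as.matrix(features)
  if (!ncol(features))
    return(data.frame(feature = character(), cutpoint = numeric(),
                      statistic = numeric(), hr = numeric(),
                      ciLower = numeric(), ciUpper = numeric(),
                      coxP = numeric(), logrankP = numeric(),
                      significant = logical(), failed = logical()))
  if (nrow(features) != nrow(surv))
    stop("features must align with the survival table")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("feature_", seq_len(ncol(features)))

  rows <- lapply(colnames(features), function(f) {
    st <- cbind(surv[, c("time", "event")], score = features[, f])
    res <- tryCatch(maxstatCutpoint(st, minProp, minGroup),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(feature = f, cutpoint = NA_real_,
                        statistic = NA_real_, hr = NA_real_,
                        ciLower = NA_real_, ciUpper = NA_real_,
                        coxP = NA_real_, logrankP = NA_real_,
                        significant = FALSE, failed = TRUE,
                        stringsAsFactors = FALSE))
    data.frame(feature = f, cutpoint = res@cutpoint,
               statistic = res@statistic, hr = res@hr,
               ciLower = res@ciLower, ciUpper = res@ciUpper,
               coxP = res@coxP, logrankP = res@logrankP,
               significant = res@coxP < alpha, failed = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$hr), -ifelse(is.na(out$hr), -Inf, out$hr)), ]
  rownames(out) <- NULL
  out
}
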
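#' Dichotomize a biomarker at a quantile threshold
#'
#' Splits continuous values at a linear-interpolation (type-7) quantile,
#' by default the 75th percentile; values strictly above the threshold are
#' labeled "high", all others "low".
#'
#' @param values numeric vector (>= 4 finite values required).
#' @param quantile probability of the threshold quantile (default 0.75).
#' @return list with \code{threshold} and \code{labels} (factor low/high).
#' @examples
#' dichotomize(1:8)  # threshold 6.25; 7 and 8 are "high"
#' @export
dichotomize <- function(values, quantile = 0.75) {
  v <- values[is.finite(values)]
  if (length(v) < 4)
    stop("insufficient data: need at least 4 finite values")
  thr <- unname(stats::quantile(v, probs = quantile, type = 7))
  list(threshold = thr,
       labels = factor(ifelse(values > thr, "high", "low"),
                       levels = c("low", "high")))
}

#' Kaplan-Meier estimate of a survival endpoint
#'
#' Product-limit estimate with Greenwood-based (log-transformed)
#' confidence band, computed via \code{survival::survfit}.
#'
#' @param times follow-up times (months, >= 0).
#' @param events event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param conf confidence level.
#' @return a \linkS4class{SurvivalCurve}.
#' @export
kmFit <- function(times, events, conf = 0.95) {
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative")
  if (length(times) != length(events)) stop("times and events must align")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.int = conf, conf.type = "log")
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  medCI <- c(unname(stats::quantile(fit, probs = 0.5)$lower),
             unname(stats::quantile(fit, probs = 0.5)$upper))
  new("SurvivalCurve", time = fit$time, surv = fit$surv,
      lower = ifelse(is.na(fit$lower), 0, fit$lower),
      upper = ifelse(is.na(fit$upper), 1, fit$upper),
      nRisk = fit$n.risk, nEvent = fit$n.event,
      median = as.numeric(med), medianCI = as.numeric(medCI), fit = fit)
}

#' Survival probability at given times
#'
#' Right-continuous step-function lookup on a fitted curve (e.g. at 24 and
#' 60 months).
#'
#' @param curve a \linkS4class{SurvivalCurve}.
#' @param at numeric times.
#' @return survival probabilities at \code{at}.
#' @export
survivalAt <- function(curve, at) {
  stopifnot(is(curve, "SurvivalCurve"))
  vapply(at, function(t) {
    i <- which(curve@time <= t)
    if (!length(i)) 1 else curve@surv[max(i)]
  }, numeric(1))
}

#' Median follow-up by the reverse Kaplan-Meier estimator
#'
#' Swaps the event and censoring indicators, so censoring (being under
#' observation) is the "event" and deaths censor: the median of the
#' resulting curve estimates the median potential follow-up time.
#'
#' @inheritParams kmFit
#' @return list with \code{median} (NA with a message when the reverse
#'   curve never reaches 0.5, e.g. all subjects died) and \code{ci}.
#' @export
reverseKMFollowup <- function(times, events, conf = 0.95) {
  rev <- kmFit(times, 1 - as.integer(as.logical(events)), conf = conf)
  if (is.na(rev@median))
    message("reverse Kaplan-Meier median not reached")
  list(median = rev@median, ci = rev@medianCI, curve = rev)
}

#' Log-rank test (with pairwise post hoc tests for > 2 groups)
#'
#' Standard log-rank chi-squared test via \code{survival::survdiff}, with
#' the usual hypergeometric variance at tied event times.  With more than
#' two groups, pairwise chi-squared post hoc comparisons are reported,
#' unadjusted by default (an optional Bonferroni correction is available).
#'
#' @inheritParams kmFit
#' @param groups group labels (>= 2 non-empty groups).
#' @param adjust "none" (default) or "bonferroni" for the pairwise p-values.
#' @return a \linkS4class{TestResult}; pairwise results, when present, in
#'   \code{@details$pairwise}.
#' @export
logrankTest <- function(times, events, groups, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("need at least 2 non-empty groups")
  groups <- droplevels(groups)
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ groups)
  df <- length(sd$n) - 1
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  gsum <- data.frame(group = names(sd$n), n = as.numeric(sd$n),
                     observed = sd$obs, expected = sd$exp)
  details <- list()
  if (df > 1) {
    lv <- levels(groups)
    prs <- utils::combn(lv, 2)
    pw <- apply(prs, 2, function(pr) {
      sel <- groups %in% pr
      sdp <- survival::survdiff(
        survival::Surv(times[sel], as.integer(events)[sel]) ~
          droplevels(groups[sel]))
      c(chisq = sdp$chisq, p = stats::pchisq(sdp$chisq, 1, lower.tail = FALSE))
    })
    pair <- data.frame(a = prs[1, ], b = prs[2, ], chisq = pw["chisq", ],
                       p = pw["p", ])
    if (adjust == "bonferroni")
      pair$p_adjusted <- stats::p.adjust(pair$p, "bonferroni")
    details$pairwise <- pair
  }
  new("TestResult", method = "log-rank test", statistic = unname(sd$chisq),
      df = df, p = p, groups = gsum, details = details)
}

#' Compare a continuous variable between groups
#'
#' Two groups: Welch's unequal-variance t-test with Cohen's d on the
#' pooled SD.  More than two groups: one-way ANOVA with eta-squared
#' (SS_between / SS_total).
#'
#' @param values numeric vector.
#' @param labels group labels; every group needs n >= 2.
#' @return a \linkS4class{TestResult}.
#' @export
compareGroups <- function(values, labels) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  ns <- table(labels)
  if (any(ns < 2)) stop("insufficient data: every group needs n >= 2")
  gsum <- do.call(rbind, lapply(levels(labels), function(l) {
    v <- values[labels == l]
    data.frame(group = l, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  if (nlevels(labels) == 2) {
    tt <- stats::t.test(values ~ labels, var.equal = FALSE)
    n1 <- gsum$n[1]; n2 <- gsum$n[2]
    sp <- sqrt(((n1 - 1) * gsum$sd[1]^2 + (n2 - 1) * gsum$sd[2]^2) /
                 (n1 + n2 - 2))
    d <- abs(gsum$mean[1] - gsum$mean[2]) / sp
    new("TestResult", method = "Welch two-sample t-test",
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, effectSize = c(d = d), groups = gsum)
  } else {
    fit <- stats::aov(values ~ labels)
    s <- summary(fit)[[1]]
    eta2 <- s["labels", "Sum Sq"] / sum(s[, "Sum Sq"])
    new("TestResult", method = "one-way ANOVA",
        statistic = s["labels", "F value"],
        df = c(s["labels", "Df"], s["Residuals", "Df"]),
        p = s["labels", "Pr(>F)"], effectSize = c(eta2 = eta2),
        groups = gsum)
  }
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return a \linkS4class{TestResult} with the correlation in
#'   \code{@effectSize["r"]}.
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must align")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  new("TestResult", method = "Pearson correlation",
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p = ct$p.value, effectSize = c(r = unname(ct$estimate)))
}

#' Compare two correlated ROC AUCs (DeLong)
#'
#' Paired comparison of two scoring rules for the same binary outcome via
#' the DeLong structural-components method with the fast mid-rank
#' algorithm (as implemented in \pkg{pROC}).  Reports both AUCs, their
#' variances and covariance, and the two-sided z-test on the difference.
#'
#' @param labels binary outcome (both classes must be present).
#' @param scoresA,scoresB paired score vectors for the same cases.
#' @return a \linkS4class{TestResult}; \code{@effectSize} carries auc_a,
#'   auc_b; variances and covariance in \code{@details}.
#' @export
delongCompare <- function(labels, scoresA, scoresB) {
  labels <- as.integer(as.factor(labels))
  if (length(unique(labels)) != 2)
    stop("labels must contain exactly two classes")
  if (length(scoresA) != length(labels) || length(scoresB) != length(labels))
    stop("scores must be paired with labels")
  rocA <- pROC::roc(labels, scoresA, quiet = TRUE, direction = "<",
                    levels = sort(unique(labels)))
  rocB <- pROC::roc(labels, scoresB, quiet = TRUE, direction = "<",
                    levels = sort(unique(labels)))
  vA <- pROC::var(rocA, method = "delong")
  vB <- pROC::var(rocB, method = "delong")
  cAB <- pROC::cov(rocA, rocB, method = "delong")
  dAuc <- as.numeric(pROC::auc(rocA)) - as.numeric(pROC::auc(rocB))
  vd <- vA + vB - 2 * cAB
  if (vd <= 0) {
    z <- 0; p <- 1
  } else {
    z <- dAuc / sqrt(vd)
    p <- 2 * stats::pnorm(-abs(z))
  }
  new("TestResult", method = "DeLong paired ROC-AUC comparison",
      statistic = z, df = NA_real_, p = p,
      effectSize = c(auc_a = as.numeric(pROC::auc(rocA)),
                     auc_b = as.numeric(pROC::auc(rocB))),
      details = list(var_a = vA, var_b = vB, cov_ab = cAB,
                     delta_auc = dAuc))
}

#' Compose survival endpoints from raw per-case event records
#'
#' Implements the endpoint definitions, all measured from the day of the
#' initial surgery (time 0):
#' \itemize{
#'   \item OS: until death from any cause, else censored at last contact.
#'   \item TCSS: until disease-related death; deaths from other causes
#'     censor at the death date.
#'   \item RFS: until the first documented local or regional recurrence;
#'     recurrence-free cases are censored at the last disease-free contact
#'     (the death date for those who died without recurrence).
#'   \item MFS: until the first documented distant metastasis, censored
#'     like RFS.
#' }
#'
#' @param records data.frame with columns \code{id},
#'   \code{death_time} (NA while alive), \code{death_cause} ("disease" or
#'   "other"), \code{recurrence_time} (NA if none),
#'   \code{metastasis_time} (NA if none), \code{last_contact}.
#' @return data.frame of \code{id} plus \code{os_time}, \code{os_event},
#'   \code{tcss_time}, \code{tcss_event}, \code{rfs_time},
#'   \code{rfs_event}, \code{mfs_time}, \code{mfs_event}.
#' @export
deriveEndpoints <- function(records) {
  need <- c("id", "death_time", "death_cause", "recurrence_time",
            "metastasis_time", "last_contact")
  if (!all(need %in% names(records)))
    stop(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  tcols <- c("death_time", "recurrence_time", "metastasis_time",
             "last_contact")
  for (cl in tcols)
    if (any(records[[cl]] < 0, na.rm = TRUE))
      stop("chronology error: event before the surgery date")
  dead <- !is.na(records$death_time)
  endTime <- ifelse(dead, records$death_time, records$last_contact)
  if (any(records$recurrence_time > endTime + 1e-9, na.rm = TRUE) ||
      any(records$metastasis_time > endTime + 1e-9, na.rm = TRUE))
    stop("chronology error: recurrence/metastasis after the last contact")
  rec <- !is.na(records$recurrence_time)
  met <- !is.na(records$metastasis_time)
  data.frame(
    id = records$id,
    os_time = endTime,
    os_event = as.integer(dead),
    tcss_time = endTime,
    tcss_event = as.integer(dead & records$death_cause == "disease"),
    rfs_time = ifelse(rec, records$recurrence_time, endTime),
    rfs_event = as.integer(rec),
    mfs_time = ifelse(met, records$metastasis_time, endTime),
    mfs_event = as.integer(met),
    stringsAsFactors = FALSE)
}
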
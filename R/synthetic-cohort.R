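#' Default per-pT group marginals of the synthetic cohort
#'
#' Composition 40/39/17/4 over pT1..pT4a with the published per-group MPP
#' and tumor-thickness means and standard deviations.
#'
#' @return data.frame with columns pT, prop, mppMean, mppSd, thickMean,
#'   thickSd.
#' @export
defaultCohortGroups <- function() {
  data.frame(
    pT = c("pT1", "pT2", "pT3", "pT4a"),
    prop = c(0.40, 0.39, 0.17, 0.04),
    mppMean = c(3.39, 4.04, 3.94, 4.33),
    mppSd = c(0.65, 0.46, 0.54, 0.42),
    thickMean = c(4436, 8776, 9267, 11436),
    thickSd = c(2759, 3446, 2549, 2017),
    stringsAsFactors = FALSE)
}

#' Default survival anchors per endpoint and MPP stratum
#'
#' 2-year and 5-year survival probabilities for the low (MPP <= threshold)
#' and high (MPP > threshold) strata.  OS and tumor-specific survival come
#' from the published stratum-level tables; relapse-free survival uses the
#' pooled cohort value for both strata (the stratum difference was not
#' significant), and distant-metastasis-free survival uses the close-margin
#' subgroup values (the low stratum experienced no metastases at all,
#' hence a zero hazard).
#'
#' @return named list of endpoint anchor lists.
#' @export
defaultAnchors <- function() {
  list(
    os = list(low = c(0.874, 0.735), high = c(0.603, 0.413)),
    tcss = list(low = c(0.936, 0.919), high = c(0.691, 0.655)),
    rfs = list(low = c(0.88, 0.749), high = c(0.88, 0.749)),
    mfs = list(low = c(1, 1), high = c(0.85, 0.707)))
}

# Solve the within-case latent normal correlation so the POOLED Pearson
# correlation between MPP and thickness equals `rho`. Pooled covariance
# decomposes into the between-group mean structure plus the within-group
# part E_g[rho* sd_m sd_t]; pooled variances likewise.
solveLatentRho <- function(groups, rho) {
  w <- groups$prop
  mm <- sum(w * groups$mppMean); mt <- sum(w * groups$thickMean)
  covB <- sum(w * (groups$mppMean - mm) * (groups$thickMean - mt))
  vM <- sum(w * groups$mppSd^2) + sum(w * (groups$mppMean - mm)^2)
  vT <- sum(w * groups$thickSd^2) + sum(w * (groups$thickMean - mt)^2)
  eSS <- sum(w * groups$mppSd * groups$thickSd)
  (rho * sqrt(vM * vT) - covB) / eSS
}

#' Build a synthetic-cohort configuration
#'
#' All defaults are the study conditions: 100 cases with the published pT
#' composition and per-group (MPP, thickness) normal marginals, pooled
#' MPP-thickness correlation 0.736 (induced through a Gaussian copula whose
#' within-case latent correlation is solved from the group structure at
#' configuration time), MPP dichotomization threshold 4.2 for the survival
#' strata, piecewise-exponential survival with knots at 24 and 60 months
#' passing through the published 2-/5-year anchors, and uniform
#' administrative censoring on (2.2, 185) months, which yields a reverse
#' Kaplan-Meier median follow-up of 93.6 months and a maximum of 185.
#'
#' @param nCases cohort size.
#' @param groups per-group marginals, see \code{\link{defaultCohortGroups}}.
#' @param rho target pooled Pearson correlation of MPP and thickness.
#' @param threshold MPP cut separating the survival strata.
#' @param anchors per-endpoint survival anchors, see
#'   \code{\link{defaultAnchors}}.
#' @param censorRange range of the uniform censoring time, months.
#' @param observerSd SD (percentage points) of the emulated pathologist's
#'   naked-eye stromal estimate around the true stromal ratio; a
#'   plausibility value, not a fitted constant.
#' @return a \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(nCases = 100, groups = defaultCohortGroups(),
                         rho = 0.736, threshold = 4.2,
                         anchors = defaultAnchors(),
                         censorRange = c(2.2, 185), observerSd = 7) {
  latent <- solveLatentRho(groups, rho)
  new("CohortConfig", nCases = as.integer(nCases), groups = groups,
      rho = rho, latentRho = latent, threshold = threshold,
      anchors = anchors, censorRange = as.numeric(censorRange),
      observerSd = observerSd)
}

# Draw a binary label whose latent liability correlates with the pooled
# MPP z-score; rLatent controls the label/MPP association strength.
latentLabel <- function(z, rLatent, pHigh = 0.5, levels) {
  liab <- rLatent * z + sqrt(1 - rLatent^2) * stats::rnorm(length(z))
  factor(ifelse(liab > stats::qnorm(1 - pHigh), levels[2], levels[1]),
         levels = levels)
}

#' Generate one synthetic clinicopathologic cohort
#'
#' Per case: a pT group drawn from the configured composition; (MPP,
#' thickness) from a Gaussian copula with group-specific normal marginals
#' and the calibrated latent correlation (jointly resampled while MPP < 0
#' or thickness <= 0); categorical labels (grade, nodal status, growth and
#' infiltration pattern, margin stratum) from latent-liability models tied
#' to the pooled MPP z-score; a true stromal ratio plus a noisy emulated
#' pathologist estimate; and four survival endpoints composed from latent
#' competing event times (tumor-specific death, other-cause death,
#' recurrence, distant metastasis) with uniform administrative censoring,
#' assembled through \code{\link{deriveEndpoints}}.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param seed integer seed; identical seeds reproduce the table exactly.
#' @return data.frame with one row per case (covariates, MPP, and
#'   \code{*_time}/\code{*_event} columns for os, tcss, rfs, mfs).
#' @export
generateCohort <- function(config = cohortConfig(), seed = 1) {
  stopifnot(is(config, "CohortConfig"))
  set.seed(as.integer(seed))
  g <- config@groups
  n <- config@nCases
  counts <- stats::rmultinom(1, n, g$prop)[, 1]
  gi <- rep(seq_len(nrow(g)), counts)

  rho <- config@latentRho
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  mpp <- g$mppMean[gi] + g$mppSd[gi] * z1
  thick <- g$thickMean[gi] + g$thickSd[gi] * z2
  # truncate MPP at 0 by joint resampling (negligible mass at the
  # configured marginals, so the copula and marginals stay calibrated);
  # thickness is floored at 1 um instead -- resampling on the thickness
  # tail would bias the MPP marginal through the copula
  bad <- which(mpp < 0)
  while (length(bad)) {
    z1b <- stats::rnorm(length(bad))
    z2b <- rho * z1b + sqrt(1 - rho^2) * stats::rnorm(length(bad))
    mpp[bad] <- g$mppMean[gi[bad]] + g$mppSd[gi[bad]] * z1b
    thick[bad] <- g$thickMean[gi[bad]] + g$thickSd[gi[bad]] * z2b
    bad <- bad[mpp[bad] < 0]
  }
  thick <- pmax(thick, 1)

  zPool <- (mpp - mean(mpp)) / stats::sd(mpp)
  growth <- latentLabel(zPool, 0.47, 0.5, c("cohesive", "discohesive"))
  infiltration <- latentLabel(zPool, 0.35, 0.5, c("compact", "discontinuous"))
  margin <- factor(sample(c("R0fm", "R0cm"), n, TRUE, c(0.6, 0.4)),
                   levels = c("R0fm", "R0cm"))
  # ordinal grade via thresholds on a liability correlated with MPP
  gl <- 0.3 * zPool + sqrt(1 - 0.3^2) * stats::rnorm(n)
  gcut <- stats::qnorm(cumsum(c(0.09, 0.52)))
  grade <- cut(gl, c(-Inf, gcut, Inf), labels = c("G1", "G2", "G3"))
  nl <- 0.33 * zPool + sqrt(1 - 0.33^2) * stats::rnorm(n)
  ncut <- stats::qnorm(cumsum(c(0.67, 0.14)))
  nodal <- cut(nl, c(-Inf, ncut, Inf),
               labels = c("none", "occult", "manifest"))
  pn <- factor(ifelse(nodal == "none",
                      sample(c("pN0", "pNX"), n, TRUE, c(0.65, 0.35)),
                      ifelse(nodal == "occult",
                             sample(c("pN+", "pNX"), n, TRUE, c(0.85, 0.15)),
                             "pN+")),
               levels = c("pN0", "pNX", "pN+"))

  stromaTrue <- pmin(95, pmax(2, stats::rnorm(n, 35, 15)))
  stromaPath <- pmin(100, pmax(0, stromaTrue +
                                 stats::rnorm(n, 0, config@observerSd)))

  stratum <- ifelse(mpp > config@threshold, "high", "low")
  a <- config@anchors
  tT <- tO <- tR <- tM <- numeric(n)
  for (s in c("low", "high")) {
    idx <- which(stratum == s)
    if (!length(idx)) next
    hT <- anchorsToHazards(a$tcss[[s]][1], a$tcss[[s]][2])
    hOS <- anchorsToHazards(a$os[[s]][1], a$os[[s]][2])
    hO <- pmax(hOS - hT, 0)  # other-cause hazard = OS-implied minus tumor-specific
    hR <- anchorsToHazards(a$rfs[[s]][1], a$rfs[[s]][2])
    hM <- anchorsToHazards(a$mfs[[s]][1], a$mfs[[s]][2])
    tT[idx] <- rPiecewiseExp(length(idx), c(24, 60), hT)
    tO[idx] <- rPiecewiseExp(length(idx), c(24, 60), hO)
    tR[idx] <- rPiecewiseExp(length(idx), c(24, 60), hR)
    tM[idx] <- rPiecewiseExp(length(idx), c(24, 60), hM)
  }
  cens <- stats::runif(n, config@censorRange[1], config@censorRange[2])
  death <- pmin(tT, tO)
  cause <- ifelse(tT <= tO, "disease", "other")
  obsEnd <- pmin(death, cens)
  records <- data.frame(
    id = sprintf("case%03d", seq_len(n)),
    death_time = ifelse(death <= cens, death, NA),
    death_cause = ifelse(death <= cens, cause, NA),
    recurrence_time = ifelse(tR < obsEnd, tR, NA),
    metastasis_time = ifelse(tM < obsEnd, tM, NA),
    last_contact = obsEnd,
    stringsAsFactors = FALSE)
  ep <- deriveEndpoints(records)

  cbind(
    data.frame(id = records$id, pT = factor(g$pT[gi], levels = g$pT),
               mpp = mpp, thickness_um = thick, grade = grade,
               nodal = nodal, pn = pn, growth = growth,
               infiltration = infiltration, margin = margin,
               stroma_pct_true = stromaTrue,
               stroma_pct_pathologist = stromaPath,
               stringsAsFactors = FALSE),
    ep[, -1])
}
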
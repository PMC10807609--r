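test_that("quantile dichotomization uses linear interpolation and strict inequality", {
  d <- dichotomize(1:8)
  expect_equal(d$threshold, 6.25)
  expect_identical(which(d$labels == "high"), c(7L, 8L))
  same <- dichotomize(rep(3.3, 10))
  expect_true(all(same$labels == "low"))
  expect_error(dichotomize(c(1, 2, 3)), "at least 4")
})

test_that("Kaplan-Meier equals the empirical survival function without censoring", {
  km <- kmFit(1:4, rep(1, 4))
  expect_equal(survivalAt(km, 2.5), 0.5)
  expect_equal(survivalAt(km, c(0, 1, 2, 3, 4)), c(1, .75, .5, .25, 0))
  # larger uncensored sample: exact agreement with the ECDF complement
  set.seed(1)
  t <- rexp(200)
  km2 <- kmFit(t, rep(1, 200))
  at <- quantile(t, c(.1, .5, .9))
  expect_equal(survivalAt(km2, at), 1 - ecdf(t)(at), ignore_attr = TRUE)
})

test_that("Kaplan-Meier handles censoring as in the hand-computed toy example", {
  # times 1, 2+, 3, 4, 5+, 6: S = 5/6, 5/8, 5/12, 0
  km <- kmFit(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 1, 0, 1))
  expect_equal(survivalAt(km, c(1, 3, 4, 6)),
               c(5 / 6, 5 / 8, 5 / 12, 0), tolerance = 1e-12)
  all_cens <- kmFit(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(all_cens@surv == 1))
  expect_error(kmFit(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("reverse Kaplan-Meier recovers the follow-up distribution", {
  rk <- reverseKMFollowup(c(10, 20, 30, 40), c(0, 0, 0, 0))
  expect_equal(rk$median, 25)
  expect_message(rkAll <- reverseKMFollowup(c(1, 2, 3, 4), c(1, 1, 1, 1)),
                 "not reached")
  expect_true(is.na(rkAll$median))
})

test_that("log-rank test matches a hand-computed observed-expected table", {
  # independent oracle: direct accumulation of O-E and hypergeometric
  # variance over distinct event times
  logrankOracle <- function(t1, e1, t2, e2) {
    tt <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
    O1 <- E1 <- V <- 0
    for (s in tt) {
      n1 <- sum(t1 >= s); n2 <- sum(t2 >= s); n <- n1 + n2
      d1 <- sum(t1 == s & e1 == 1); d2 <- sum(t2 == s & e2 == 1)
      d <- d1 + d2
      O1 <- O1 + d1
      E1 <- E1 + d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
    }
    (O1 - E1)^2 / V
  }
  t1 <- c(3, 5, 8, 10, 14); e1 <- c(1, 1, 0, 1, 1)
  t2 <- c(2, 6, 7, 11, 15); e2 <- c(1, 0, 1, 1, 0)
  want <- logrankOracle(t1, e1, t2, e2)
  got <- logrankTest(c(t1, t2), c(e1, e2), rep(c("a", "b"), each = 5))
  expect_equal(got@statistic, want, tolerance = 1e-10)
  expect_equal(got@df, 1)
})

test_that("log-rank on a duplicated group is exactly null", {
  t <- c(3, 5, 7, 9, 11); e <- c(1, 0, 1, 1, 0)
  r <- logrankTest(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(r@statistic, 0, tolerance = 1e-12)
  expect_equal(r@p, 1)
  expect_error(logrankTest(t, e, rep("a", 5)), "2 non-empty")
})

test_that("pairwise post hoc tests appear for more than two groups", {
  set.seed(11)
  t <- rexp(60); e <- rbinom(60, 1, 0.7); g <- rep(c("a", "b", "c"), 20)
  r <- logrankTest(t, e, g)
  expect_equal(r@df, 2)
  pw <- r@details$pairwise
  expect_equal(nrow(pw), 3)
  radj <- logrankTest(t, e, g, adjust = "bonferroni")
  expect_true(all(radj@details$pairwise$p_adjusted >=
                    radj@details$pairwise$p - 1e-15))
})

test_that("log-rank p-values are approximately uniform under permutation", {
  set.seed(12)
  t <- rexp(40); e <- rbinom(40, 1, 0.8)
  ps <- replicate(400, {
    g <- sample(rep(c("a", "b"), each = 20))
    logrankTest(t, e, g)@p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("two-group comparison is Welch t with pooled-SD Cohen's d", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  r <- compareGroups(v, g)
  expect_equal(unname(r@effectSize["d"]), 3)  # |1-2|... (means 2 vs 5, sp 1)
  expect_equal(r@method, "Welch two-sample t-test")
  # identical groups: d = 0
  r0 <- compareGroups(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(unname(r0@effectSize["d"]), 0)
  expect_error(compareGroups(c(1, 2, 3), c("a", "a", "b")), "n >= 2")
})

test_that("multi-group comparison is one-way ANOVA with eta-squared", {
  set.seed(13)
  v <- c(rnorm(20, 0), rnorm(20, 0.5), rnorm(20, 1))
  g <- rep(c("a", "b", "c"), each = 20)
  r <- compareGroups(v, g)
  expect_equal(r@method, "one-way ANOVA")
  a <- summary(stats::aov(v ~ factor(g)))[[1]]
  expect_equal(r@statistic, a["factor(g)", "F value"])
  expect_equal(unname(r@effectSize["eta2"]),
               a[1, "Sum Sq"] / sum(a[, "Sum Sq"]))
  # identical group distributions: eta2 equals 0 up to float tolerance
  r0 <- compareGroups(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_lt(unname(r0@effectSize["eta2"]), 1e-12)
})

test_that("growth-pattern group simulation yields a moderate-to-large effect", {
  # simulate two groups at the configured discohesive/cohesive marginals
  # and study-like sizes; Cohen's d should land near its closed-form value
  dTheory <- (3.99 - 3.51) / sqrt((0.57^2 + 0.62^2) / 2)  # about 0.8
  set.seed(14)
  ds <- replicate(200, {
    x <- rnorm(49, 3.99, 0.57)
    y <- rnorm(48, 3.51, 0.62)
    r <- compareGroups(c(x, y), rep(c("d", "c"), c(49, 48)))
    unname(r@effectSize["d"])
  })
  expect_lt(abs(mean(ds) - dTheory), 0.1)
  expect_gt(dTheory, 0.7)
})

test_that("Pearson correlation matches the closed-form estimate", {
  expect_equal(unname(pearsonCor(1:10, 1:10)@effectSize["r"]), 1)
  expect_equal(unname(pearsonCor(1:10, -(1:10))@effectSize["r"]), -1)
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4)
  y <- c(2.0, 3.1, 2.8, 6.0, 3.9)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(pearsonCor(x, y)@effectSize["r"]), hand,
               tolerance = 1e-12)
  expect_error(pearsonCor(rep(1, 5), 1:5), "zero variance")
})

test_that("DeLong comparison handles degenerate and perfect cases", {
  lab <- rep(0:1, each = 10)
  s <- c(rnorm(10), rnorm(10) + 1)
  same <- delongCompare(lab, s, s)
  expect_equal(same@details$delta_auc, 0)
  expect_equal(same@p, 1)
  # a perfectly separating score has AUC 1 (pROC warns that its DeLong
  # variance degenerates to 0 there)
  perfect <- suppressWarnings(delongCompare(lab, c(1:10, 21:30) / 30, s))
  expect_equal(unname(perfect@effectSize["auc_a"]), 1)
  expect_error(delongCompare(rep(1, 10), s[1:10], s[1:10]), "two classes")
})

test_that("DeLong variance agrees with resampling oracles on an n = 30 fixture", {
  set.seed(42)
  lab <- rep(0:1, each = 15)
  sa <- rnorm(30) + 1.2 * lab
  sb <- 0.6 * sa + rnorm(30) * 0.8 + 0.5 * lab
  dl <- delongCompare(lab, sa, sb)
  vDelong <- dl@details$var_a + dl@details$var_b - 2 * dl@details$cov_ab
  # jackknife oracle (deterministic)
  n <- 30
  jk <- vapply(seq_len(n), function(i) {
    empiricalAUC(lab[-i], sa[-i]) - empiricalAUC(lab[-i], sb[-i])
  }, numeric(1))
  vJack <- (n - 1) / n * sum((jk - mean(jk))^2)
  expect_lt(abs(vJack / vDelong - 1), 0.25)
  # stratified bootstrap oracle
  set.seed(7)
  bs <- replicate(2000, {
    i <- c(sample(which(lab == 0), 15, TRUE), sample(which(lab == 1), 15, TRUE))
    empiricalAUC(lab[i], sa[i]) - empiricalAUC(lab[i], sb[i])
  })
  expect_lt(abs(stats::var(bs) / vDelong - 1), 0.3)
  # the reported AUCs equal the empirical mid-rank AUCs
  expect_equal(unname(dl@effectSize["auc_a"]), empiricalAUC(lab, sa))
  expect_equal(unname(dl@effectSize["auc_b"]), empiricalAUC(lab, sb))
})

test_that("DeLong p-values are approximately uniform under label pairing permutations", {
  set.seed(15)
  n <- 40
  base <- rnorm(n)
  ps <- replicate(500, {
    lab <- sample(rep(0:1, each = n / 2))
    sa <- base + rnorm(n) * 0.5
    sb <- base + rnorm(n) * 0.5
    delongCompare(lab, sa, sb)@p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("endpoint derivation follows the stated censoring rules", {
  rec <- data.frame(
    id = c("a", "b", "c"),
    death_time = c(30, NA, 20),
    death_cause = c("other", NA, "disease"),
    recurrence_time = c(NA, NA, NA),
    metastasis_time = c(NA, NA, 12),
    last_contact = c(30, 24, 20),
    stringsAsFactors = FALSE)
  ep <- deriveEndpoints(rec)
  # death from another cause: OS event, TCSS censored at the same time
  expect_equal(ep$os_event[1], 1L); expect_equal(ep$os_time[1], 30)
  expect_equal(ep$tcss_event[1], 0L); expect_equal(ep$tcss_time[1], 30)
  # alive and disease-free: all endpoints censored at last contact
  expect_true(all(ep[2, c("os_event", "tcss_event", "rfs_event",
                          "mfs_event")] == 0))
  expect_true(all(ep[2, c("os_time", "tcss_time", "rfs_time",
                          "mfs_time")] == 24))
  # metastasis then disease death: MFS event at 12, OS/TCSS event at 20
  expect_equal(ep$mfs_event[3], 1L); expect_equal(ep$mfs_time[3], 12)
  expect_equal(ep$os_time[3], 20); expect_equal(ep$tcss_event[3], 1L)
  bad <- rec; bad$death_time[1] <- -2
  expect_error(deriveEndpoints(bad), "chronology")
})
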
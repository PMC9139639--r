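line_rec <- function(start, est_end) {
  data.frame(start_date = start, est_end_date = est_end)
}

test_that("TTD endpoint and censoring follow the discontinuation rule", {
  # confirmed discontinuation: >= 90 days of follow-up past the end
  r <- compute_ttd(line_rec(0, 120), last_claim = 300, death = NA)
  expect_equal(r, list(time = 120, event = TRUE))
  # insufficient follow-up censors at the estimated end
  r <- compute_ttd(line_rec(0, 120), last_claim = 150, death = NA)
  expect_equal(r, list(time = 120, event = FALSE))
  # death beats everything
  r <- compute_ttd(line_rec(0, 120), last_claim = 300, death = 60)
  expect_equal(r, list(time = 60, event = TRUE))
  # loss of claims before the end of therapy censors at last claim
  r <- compute_ttd(line_rec(0, 120), last_claim = 90, death = NA)
  expect_equal(r, list(time = 90, event = FALSE))
  expect_error(compute_ttd(line_rec(100, 120), last_claim = 50, death = NA),
               "precedes")
})

test_that("OS runs report-to-death with registry-authoritative deaths", {
  expect_equal(compute_os(0, death = 200, last_claim = 300),
               list(time = 200, event = TRUE))
  expect_equal(compute_os(0, death = NA, last_claim = 400),
               list(time = 400, event = FALSE))
  # death after the last claim is still an event
  expect_equal(compute_os(0, death = 500, last_claim = 450),
               list(time = 500, event = TRUE))
  expect_error(compute_os(100, death = 50, last_claim = 300), "precedes")
})

test_that("TTD/OS agree with a straight-line re-implementation on random triples", {
  set.seed(99)
  for (i in 1:1000) {
    start <- sample.int(100, 1)
    est_end <- start + sample.int(300, 1)
    last_claim <- start + sample.int(500, 1) - 1L
    death <- if (runif(1) < 0.4) start + sample.int(500, 1) else NA
    got <- compute_ttd(line_rec(start, est_end), last_claim, death)
    expect_equal(got, ttd_oracle(start, est_end, last_claim, death))
    report <- start - sample.int(60, 1)
    death_os <- if (!is.na(death) && death < report) NA else death
    got_os <- compute_os(report, death_os, max(last_claim, report))
    expect_equal(got_os, os_oracle(report, death_os, max(last_claim, report)))
  }
})

test_that("KM reproduces closed forms and hand product-limits", {
  r <- data.frame(time = c(1, 2, 3), event = TRUE)
  fit <- km_fit(r)
  expect_equal(fit$fit$surv, c(2 / 3, 1 / 3, 0))
  # censoring: events at 1 and 2, one subject censored later at 2.5, so two
  # remain at risk at the second event -> S(2) = (2/3)*(1/2)
  r2 <- data.frame(time = c(1, 2, 2.5), event = c(TRUE, TRUE, FALSE))
  fit2 <- km_fit(r2)
  expect_equal(fit2$fit$surv[fit2$fit$time == 2], 1 / 3)
  # censoring before the last event removes that subject from the risk set
  r2b <- data.frame(time = c(1, 1.5, 2), event = c(TRUE, FALSE, TRUE))
  fit2b <- km_fit(r2b)
  expect_equal(fit2b$fit$surv[fit2b$fit$time == 2], 0)
  # all censored: survival stays 1, median undefined
  r3 <- data.frame(time = c(5, 10), event = FALSE)
  fit3 <- km_fit(r3)
  expect_true(all(fit3$fit$surv == 1))
  expect_true(is.na(fit3$medians$median_months))
  # no censoring: KM equals the empirical survival function
  set.seed(1)
  tt <- rexp(40)
  fit4 <- km_fit(data.frame(time = tt, event = TRUE))
  emp <- vapply(fit4$fit$time, function(t) mean(tt > t), numeric(1))
  expect_equal(fit4$fit$surv, emp)
  # agreement with the hand-rolled product-limit on a censored sample
  set.seed(2)
  tt <- round(rexp(30), 2)
  ev <- runif(30) < 0.7
  fit5 <- km_fit(data.frame(time = tt, event = ev))
  orc <- km_oracle(tt, ev)
  expect_equal(fit5$fit$surv[fit5$fit$n.event > 0], orc$surv)
})

test_that("log-rank is null on identical groups and matches the direct statistic", {
  base <- data.frame(time = c(2, 4, 6, 8), event = c(TRUE, TRUE, FALSE, TRUE))
  two <- rbind(cbind(base, group = "a"), cbind(base, group = "b"))
  lr <- logrank_test(two)
  expect_equal(lr$chisq, 0, tolerance = 1e-10)
  expect_equal(lr$p.value, 1, tolerance = 1e-10)
  expect_error(logrank_test(cbind(base, group = "a")), "two groups")
  # statistic equals the direct O-E/V computation
  set.seed(5)
  d <- data.frame(time = c(1, 3, 4, 6, 8, 9),
                  event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
                  group = c("a", "b", "a", "b", "a", "b"))
  expect_equal(logrank_test(d)$chisq,
               logrank_stat_oracle(d$time, d$event, d$group),
               tolerance = 1e-8)
})

test_that("log-rank p is consistent with the exact permutation distribution", {
  set.seed(8)
  for (i in 1:5) {
    n <- 6
    d <- data.frame(time = sample.int(20, n),
                    event = runif(n) < 0.8,
                    group = rep(c("a", "b"), each = 3))
    if (sum(d$event) == 0) next
    # the statistic itself must agree with the direct O-E/V computation on
    # every one of the choose(6,3) relabelings (an exact oracle)
    combs <- utils::combn(n, 3)
    for (k in seq_len(ncol(combs))) {
      g <- rep("b", n); g[combs[, k]] <- "a"
      d2 <- d; d2$group <- g
      expect_equal(logrank_test(d2)$chisq,
                   logrank_stat_oracle(d2$time, d2$event, d2$group),
                   tolerance = 1e-8)
    }
    # the asymptotic p tracks the exact permutation p up to the chi-square
    # approximation error, which dominates at six records (permutation
    # resolution is 1/20)
    p_asym <- logrank_test(d)$p.value
    p_perm <- logrank_perm_oracle(d$time, d$event, d$group)
    expect_lt(abs(p_asym - p_perm), 0.3)
  }
})

test_that("log-rank detects separated exponential groups", {
  set.seed(21)
  hits <- 0
  for (i in 1:50) {
    d <- data.frame(
      time = c(rexp(125, 1), rexp(125, 1.6), rexp(125, 2.2), rexp(125, 2.2)),
      event = TRUE,
      group = rep(c("g1", "g2", "g3", "g4"), each = 125))
    if (logrank_test(d)$p.value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 48)  # >= 95% power expected at these separations
})

test_that("Cox matches the direct partial-likelihood maximiser and recovers HRs", {
  # toy instance against direct optimisation of the Breslow partial likelihood
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                  event = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
                  group = c("b", "a", "b", "a", "a", "b"))
  fit <- cox_ph(d, reference = "a")
  beta_hat <- log(fit$pairwise$hr[fit$pairwise$group == "b"])
  beta_orc <- cox_mle_oracle(d$time, d$event, as.numeric(d$group == "b"))
  expect_equal(beta_hat, beta_orc, tolerance = 1e-4)
  # null case: CI covers 1
  set.seed(31)
  d0 <- data.frame(time = rexp(1000), event = TRUE,
                   group = rep(c("a", "b"), 500))
  pw0 <- cox_ph(d0)$pairwise
  expect_true(pw0$lower[1] < 1 & pw0$upper[1] > 1)
  # true HR 2 recovered within 10%
  set.seed(32)
  d2 <- data.frame(time = c(rexp(1000, 1), rexp(1000, 2)), event = TRUE,
                   group = rep(c("a", "b"), each = 1000))
  hr <- cox_ph(d2)$pairwise
  hr <- hr$hr[hr$group == "b"]
  expect_lt(abs(hr - 2) / 2, 0.1)
  # a level with no events is flagged non-estimable
  d3 <- data.frame(time = c(1, 2, 3, 4), event = c(TRUE, TRUE, FALSE, FALSE),
                   group = c("a", "a", "b", "b"))
  expect_false(all(suppressWarnings(cox_ph(d3))$pairwise$estimable))
})

test_that("two-proportion tests: z closed form, Fisher vs enumeration, auto rule", {
  same <- two_prop_test(20, 50, 40, 100, method = "z")
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # large-sample comparison is highly significant
  expect_lt(two_prop_test(97, 138, 410, 926, method = "z")$p.value, 0.001)
  # Fisher agrees with full hypergeometric enumeration on random tables
  set.seed(13)
  for (i in 1:50) {
    n1 <- sample.int(15, 1); n2 <- sample.int(15, 1)
    x1 <- sample.int(n1 + 1, 1) - 1L; x2 <- sample.int(n2 + 1, 1) - 1L
    expect_equal(two_prop_test(x1, n1, x2, n2, method = "fisher")$p.value,
                 fisher_oracle(x1, n1, x2, n2), tolerance = 1e-8)
  }
  # auto picks Fisher when an expected cell drops below 5
  expect_equal(two_prop_test(1, 8, 3, 9, method = "auto")$method, "fisher")
  expect_equal(two_prop_test(40, 100, 50, 100, method = "auto")$method, "z")
  expect_error(two_prop_test(0, 0, 1, 5), "at least one")
})
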
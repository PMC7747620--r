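test_that("median stratification follows the strict-above-median tie rule", {
  s <- median_stratify(c(s1 = 5, s2 = 1, s3 = 3, s4 = 4))  # median 3.5
  expect_equal(names(s$labels)[s$labels == "high"], c("s1", "s4"))
  expect_equal(names(s$labels)[s$labels == "low"], c("s2", "s3"))
  expect_equal(s$threshold, 3.5)

  # ties at the median go low
  s2 <- median_stratify(c(s1 = 1, s2 = 2, s3 = 2, s4 = 9))  # median 2
  expect_equal(names(s2$labels)[s2$labels == "high"], "s4")
  expect_equal(sum(s2$labels == "low"), 3L)
  expect_true(s2$n_low >= s2$n_high)

  expect_error(median_stratify(c(7, 7, 7, 7)), "degenerate")
  expect_error(median_stratify(c(1, 2, 3)), ">= 4 samples")
})

test_that("combo stratification reduces to the single split and labels mixed", {
  v <- c(s1 = 5, s2 = 1, s3 = 3, s4 = 4)
  s1 <- median_stratify(v)
  expect_equal(combo_stratify(list(s1))$labels, s1$labels)

  v2 <- c(s1 = 1, s2 = 9, s3 = 8, s4 = 2)
  s2 <- median_stratify(v2)
  cs <- combo_stratify(list(s1, s2))
  # s1 is high for m1 (5 > 3.5) but low for m2 (1 <= 5)
  expect_equal(as.character(cs$labels[["s1"]]), "mixed")
  expect_equal(as.character(cs$labels[["s4"]]), "mixed")
  expect_equal(cs$n_high + cs$n_low, 0L)
  expect_true(attr(cs, "degenerate"))
})

test_that("all-high group size of independent 50/50 splits matches the binomial expectation", {
  # 2 independent miRNAs over 400 samples: E[n_high] = 400/4 = 100,
  # sd = sqrt(400 * 1/4 * 3/4) ~ 8.66; check within 3 sd over seeds
  set.seed(101)
  for (i in 1:5) {
    x <- matrix(rlnorm(800), nrow = 2,
                dimnames = list(c("a", "b"), paste0("s", 1:400)))
    cs <- combo_stratify(list(median_stratify(x[1, ]),
                              median_stratify(x[2, ])))
    expect_lt(abs(cs$n_high - 100), 3 * sqrt(400 * 0.25 * 0.75))
  }
})

test_that("Kaplan-Meier estimate matches the hand-computed product limit", {
  # all censored: flat at 1
  k0 <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(k0$surv == 1))

  # three events, no censoring: 2/3, 1/3, 0
  k1 <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k1$surv, c(2 / 3, 1 / 3, 0))

  # single subject with an event
  expect_equal(km_curve(5, 1)$surv, 0)

  # properties: non-increasing, in [0,1]; equals the empirical survival
  # function when there is no censoring
  set.seed(3)
  t <- sample(1:20, 30, replace = TRUE)
  k <- km_curve(t, rep(1, 30))
  expect_true(all(diff(k$surv) <= 1e-12))
  expect_true(all(k$surv >= 0 & k$surv <= 1))
  emp <- vapply(k$time, function(tt) mean(t > tt), 0)
  expect_equal(k$surv, emp)
})

test_that("log-rank statistic matches the hand-computed 2x2 tables and is symmetric", {
  # A events at 1,2; B events at 3,4: O_A = 2, E_A = 5/6, V = 17/36
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 5 / 6)
  expect_equal(lr$chi2, 49 / 17, tolerance = 1e-12)

  # identical groups: chi2 = 0, p = 1
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$p, 1)

  # invariant under swapping labels
  d <- random_survival_data(seed = 5)
  a <- logrank_test(d$time, d$event, d$group)
  b <- logrank_test(d$time, d$event,
                    factor(ifelse(d$group == "high", "low", "high")))
  expect_equal(a$chi2, b$chi2)

  # errors
  expect_error(logrank_test(1:4, c(1, 1, 1, 1), c("A", "A", "A", "A")),
               "two non-empty groups")
  expect_error(logrank_test(1:4, c(0, 0, 0, 0), c("A", "A", "B", "B")),
               "no information")
})

test_that("log-rank chi-square p agrees with the permutation distribution", {
  d <- random_survival_data(n = 30, seed = 11)
  lr <- logrank_test(d$time, d$event, d$group)
  p_perm <- oracle_perm_logrank(d$time, d$event, d$group, B = 2000)
  # Monte-Carlo error ~ 2 * sqrt(p(1-p)/2000)
  expect_lt(abs(lr$p - p_perm), 0.05)
})

test_that("log-rank p is invariant under monotone transforms of the expression", {
  set.seed(21)
  v <- rlnorm(40)
  names(v) <- paste0("s", 1:40)
  t <- rexp(40, 1 / 10); e <- rbinom(40, 1, 0.7); e[1] <- 1
  s_raw <- median_stratify(v)
  s_log <- median_stratify(log(v))
  s_cub <- median_stratify(v^3)
  expect_equal(s_raw$labels, s_log$labels)
  expect_equal(s_raw$labels, s_cub$labels)
  p <- vapply(list(s_raw, s_log, s_cub), function(s)
    logrank_test(t, e, s$labels)$p, 0)
  expect_equal(p[1], p[2])
  expect_equal(p[1], p[3])
})

test_that("Cox fit maximizes the partial likelihood (grid oracle) and is symmetric", {
  # identical event patterns: beta = 0, HR = 1
  f0 <- cox_binary_fit(c(1, 2, 1, 2), c(1, 1, 1, 1),
                       factor(c("high", "high", "low", "low"),
                              levels = c("high", "low")))
  expect_equal(f0$beta, 0, tolerance = 1e-8)
  expect_equal(f0$hr, 1, tolerance = 1e-8)
  expect_identical(f0$hr, exp(f0$beta))

  for (seed in c(2, 7, 13)) {
    d <- random_survival_data(n = 25, tie_prob = 0, seed = seed)
    f <- cox_binary_fit(d$time, d$event, d$group)
    b_grid <- oracle_cox_grid(d$time, d$event, d$z)
    expect_lt(abs(f$beta - b_grid), 1e-3)

    # HR(high vs low) = 1 / HR(low vs high)
    g_sw <- factor(ifelse(d$group == "high", "low", "high"),
                   levels = c("high", "low"))
    f_sw <- cox_binary_fit(d$time, d$event, g_sw)
    expect_equal(f$beta, -f_sw$beta, tolerance = 1e-10)
  }
})

test_that("Cox fit agrees with the survival package and with Breslow when untied", {
  skip_if_not_installed("survival")
  for (seed in 1:10) {
    d <- random_survival_data(n = 40, tie_prob = 0.5, seed = seed)
    f <- cox_binary_fit(d$time, d$event, d$group)
    cf <- survival::coxph(survival::Surv(d$time, d$event) ~ d$z,
                          ties = "efron")
    expect_lt(abs(f$beta - unname(coef(cf))), 1e-6)
    expect_lt(abs(f$se_beta - sqrt(vcov(cf)[1, 1])), 1e-6)
  }
  # no ties: Efron and Breslow coincide
  d <- random_survival_data(n = 30, tie_prob = 0, seed = 9)
  f <- cox_binary_fit(d$time, d$event, d$group)
  cb <- survival::coxph(survival::Surv(d$time, d$event) ~ d$z,
                        ties = "breslow")
  expect_lt(abs(f$beta - unname(coef(cb))), 1e-6)
})

test_that("monotone likelihood is reported as a capped divergence, not an error", {
  # all high-group events strictly before any low-group event, low all censored
  t <- c(1, 2, 3, 10, 11, 12)
  e <- c(1, 1, 1, 0, 0, 0)
  g <- factor(c("high", "high", "high", "low", "low", "low"),
              levels = c("high", "low"))
  f <- cox_binary_fit(t, e, g)
  expect_true(f$monotone)
  expect_lte(abs(f$beta), 15)
  expect_error(cox_binary_fit(t, rep(0, 6), g), "no information")
})
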
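test_that("median split halves distinct scores, ties go low", {
  expect_equal(unname(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  g <- median_split(c(1, 1, 1, 2))
  expect_equal(sum(g == "low"), 3)
  expect_equal(sum(g == "high"), 1)

  set.seed(51)
  g370 <- median_split(sample(seq_len(10000), 370))
  expect_equal(unname(table(g370)["high"]), 185L)
  expect_equal(unname(table(g370)["low"]), 185L)
})

test_that("administrative censoring truncates at the horizon, idempotent", {
  tbl <- data.frame(time = c(70, 60, 10), event = c(1, 1, 0))
  out <- administrative_censor(tbl, 60)
  expect_equal(out$time, c(60, 60, 10))
  expect_equal(out$event, c(0, 1, 0))
  expect_equal(administrative_censor(out, 60), out)
  # no KM support beyond the horizon
  km <- km_estimate(out)
  expect_true(all(km$time <= 60))
})

test_that("Kaplan-Meier estimate matches the hand product-limit", {
  tbl <- data.frame(time = c(1, 2), event = c(1, 1))
  km <- km_estimate(tbl)
  expect_equal(km$surv, c(0.5, 0))

  allc <- km_estimate(data.frame(time = c(1, 2, 3), event = c(0, 0, 0)))
  expect_true(all(allc$surv == 1))

  # censored-only time reduces the risk set without a step
  tbl2 <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
  km2 <- km_estimate(tbl2)
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 2], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)

  expect_error(km_estimate(data.frame(time = -1, event = 1)), "negative")
})

test_that("log-rank matches the hand hypergeometric computation", {
  # identical groups: statistic 0, p 1
  base <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0))
  dup <- rbind(cbind(base, group = "a"), cbind(base, group = "b"))
  res <- logrank_test(dup)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  # toy single-event-time case against the explicit O-E/V loop
  tbl <- data.frame(time = c(1, 5, 5, 5), event = c(1, 0, 0, 0),
                    group = c("a", "a", "b", "b"))
  res2 <- logrank_test(tbl)
  expect_equal(res2$statistic,
               oracle_logrank_chisq(tbl$time, tbl$event, tbl$group),
               tolerance = 1e-12)

  set.seed(52)
  tbl3 <- data.frame(time = rexp(30), event = rbinom(30, 1, 0.8),
                     group = rep(c("a", "b"), 15))
  expect_equal(logrank_test(tbl3)$statistic,
               oracle_logrank_chisq(tbl3$time, tbl3$event, tbl3$group),
               tolerance = 1e-10)
  expect_error(logrank_test(tbl3[tbl3$group == "a", ]), "two groups")
})

test_that("chi-squared log-rank p agrees with a permutation null", {
  set.seed(53)
  n <- 40
  tbl <- data.frame(time = rexp(n, 0.1), event = rbinom(n, 1, 0.8),
                    group = rep(c("a", "b"), each = n / 2))
  obs <- logrank_test(tbl)
  n_perm <- 10000
  stat_perm <- vapply(seq_len(n_perm), function(b) {
    oracle_logrank_chisq(tbl$time, tbl$event, sample(tbl$group))
  }, numeric(1))
  p_perm <- mean(stat_perm >= obs$statistic - 1e-12)
  mc_se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(obs$p_value - p_perm), 4 * mc_se + 0.01)
})

test_that("survival generator honours censoring and hazard direction", {
  spec <- sim_spec(seed = 54, censor_rate = 0, hazard_beta = 1)
  set.seed(54)
  scores <- rnorm(100)
  tbl <- gen_survival_cohort(spec, scores)
  expect_true(all(tbl$event == 1))
  expect_identical(tbl, gen_survival_cohort(spec, scores))

  # high-score group dies faster when beta > 0
  lower <- 0
  for (s in 1:20) {
    sp <- sim_spec(seed = s, hazard_beta = 1, n_patients = 370)
    sc <- rnorm(370)
    t2 <- administrative_censor(gen_survival_cohort(sp, sc, seed_offset = s))
    t2$group <- median_split(t2$score)
    km <- km_estimate(t2)
    s_at <- function(g) {
      k <- km[km$group == g & km$time <= 30, ]
      if (nrow(k)) k$surv[which.max(k$time)] else 1
    }
    lower <- lower + (s_at("high") < s_at("low"))
  }
  expect_gte(lower, 19)
})

test_that("median-split log-rank has correct type-I error and power", {
  reject_null <- 0
  for (s in 1:200) {
    sp <- sim_spec(seed = s, hazard_beta = 0, n_patients = 370)
    set.seed(s); sc <- rnorm(370)
    tbl <- gen_survival_cohort(sp, sc)
    res <- survival_by_median_score(tbl)
    reject_null <- reject_null + (res$logrank$p_value < 0.05)
  }
  # nominal 5% over 200 replicates (binomial SE ~1.5%)
  expect_gte(reject_null, 2)
  expect_lte(reject_null, 20)

  reject_alt <- 0
  for (s in 1:100) {
    sp <- sim_spec(seed = 5000 + s, hazard_beta = 1, n_patients = 370)
    set.seed(5000 + s); sc <- rnorm(370)
    tbl <- gen_survival_cohort(sp, sc)
    res <- survival_by_median_score(tbl)
    reject_alt <- reject_alt + (res$logrank$p_value < 0.05)
  }
  expect_gte(reject_alt, 80)
})
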
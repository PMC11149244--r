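# Kaplan-Meier cumulative incidence: hand examples, naive-oracle and
# survival::survfit agreement, tie conventions, stratification

test_that("hand product-limit example: (2,E)(4,E)(4,E)(6,C)(8,E)", {
  km <- km_cumulative_incidence(c(2, 4, 4, 6, 8), c(TRUE, TRUE, TRUE, FALSE,
                                                    TRUE))
  # S(5) = (4/5) * (2/4) = 0.4
  expect_equal(km_ci_at(km, 5), 0.6, tolerance = 1e-12)
  expect_equal(km$times, c(2, 4, 8))
  expect_equal(km$n_at_risk, c(5, 4, 1))
  expect_equal(km$n_events, c(1, 2, 1))
  expect_equal(km$cuminc[3], 1, tolerance = 1e-12)
})

test_that("without censoring the KM CI equals the empirical CDF", {
  set.seed(31)
  t <- sample(1:50, 30, replace = TRUE)
  km <- km_cumulative_incidence(t, rep(TRUE, 30))
  grid <- 0:55
  expect_equal(km_ci_at(km, grid), ecdf(t)(grid), tolerance = 1e-12)
})

test_that("all-censored input warns and returns an identically-zero CI", {
  expect_warning(km <- km_cumulative_incidence(c(3, 7), c(FALSE, FALSE)),
                 "censored")
  expect_equal(km_ci_at(km, c(0, 5, 100)), c(0, 0, 0))
})

test_that("events precede censorings at tied times", {
  # censored at 4 stays at risk for the event at 4: S(4) = 1 - 1/3
  km <- km_cumulative_incidence(c(4, 4, 5), c(TRUE, FALSE, FALSE))
  expect_equal(km_ci_at(km, 4), 1 / 3, tolerance = 1e-12)
})

test_that("KM matches the naive O(n^2) reference on 200 random datasets", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    t <- sample(1:25, n, replace = TRUE)
    ev <- runif(n) < 0.7
    if (!any(ev)) ev[1] <- TRUE
    km <- km_cumulative_incidence(t, ev)
    ref <- naive_km(t, ev)
    expect_equal(km$times, ref$times)
    expect_equal(km$cuminc, ref$cuminc, tolerance = 1e-12)
  }
})

test_that("KM agrees with survival::survfit as a second opinion", {
  skip_if_not_installed("survival")
  set.seed(77)
  for (i in 1:20) {
    n <- sample(10:100, 1)
    t <- rexp(n, 0.05)
    ev <- runif(n) < 0.6
    if (!any(ev)) ev[1] <- TRUE
    km <- km_cumulative_incidence(t, ev)
    sf <- survival::survfit(survival::Surv(t, ev) ~ 1)
    et <- sf$time[sf$n.event > 0]
    expect_equal(km$times, et)
    expect_equal(km$surv, sf$surv[sf$n.event > 0], tolerance = 1e-12)
  }
})

test_that("a late censored observation adds no event times and shrinks the CI", {
  # note: it cannot leave the CI values untouched — an extra subject sits in
  # every risk set, so each factor (1 - d_i/n_i) grows toward 1
  set.seed(5)
  t <- sample(1:30, 20, replace = TRUE)
  ev <- runif(20) < 0.6
  ev[which.max(t)] <- TRUE
  km1 <- km_cumulative_incidence(t, ev)
  km2 <- km_cumulative_incidence(c(t, max(t) + 10), c(ev, FALSE))
  expect_equal(km1$times, km2$times)
  expect_equal(km1$n_events, km2$n_events)
  expect_equal(km2$n_at_risk, km1$n_at_risk + 1L)
  expect_true(all(km2$cuminc < km1$cuminc))
  # and the curve is flat past the last event regardless
  expect_equal(km_ci_at(km2, max(t) + 9), km_ci_at(km2, max(km2$times)))
})

test_that("KM recovers an exponential CDF under heavy censoring", {
  # rate 0.1527/month, censoring uniform within 12 months:
  # CI(6 mo) = 1 - exp(-0.916) ~ 0.60
  set.seed(123)
  n <- 20000
  t_event <- rexp(n, 0.1527)
  t_cens <- runif(n, 0, 12)
  t <- pmin(t_event, t_cens)
  ev <- t_event <= t_cens
  km <- km_cumulative_incidence(t, ev)
  truth <- 1 - exp(-0.1527 * 6)
  se <- sqrt(truth * (1 - truth) / n) * 2  # censoring inflates variance
  expect_lt(abs(km_ci_at(km, 6) - truth), 3 * se + 0.005)
})

test_that("Greenwood SE stays finite at population scale", {
  # regression: n_at_risk^2 overflows 32-bit integers near n ~ 2e5
  set.seed(17)
  n <- 2e5
  t <- pmin(rexp(n, 0.01), 400)
  km <- km_cumulative_incidence(t, t < 400)
  expect_true(all(is.finite(km$se)))
  expect_true(all(km$se >= 0))
})

test_that("make_followup_observations handles events, censoring, same-day", {
  recs <- rbind(
    lab_record("A", collection_date = "2019-01-01"),
    lab_record("A", collection_date = "2019-07-01", value = "1.1"),
    lab_record("B", collection_date = "2020-05-31"),
    lab_record("C", collection_date = "2019-03-01"),
    lab_record("C", collection_date = "2019-03-01", value = "1.2"),
    lab_record("C", collection_date = "2019-09-01", value = "1.3"))
  out <- build_assessments(recs)
  obs <- make_followup_observations(out$assessments, out$records,
                                    "2021-05-31")
  obs <- obs[order(obs$patient_id), ]
  expect_equal(obs$time, c(181, 365, 184))
  expect_equal(obs$event, c(TRUE, FALSE, TRUE))  # B censored at study end
})

test_that("stratified curves respect hazard ordering and edge cases", {
  set.seed(42)
  n <- 800
  obs <- data.frame(
    patient_id = as.character(1:n),
    g_stage = rep(c("G2", "G4"), each = n / 2),
    time = c(pmin(rexp(n / 2, 0.01), 365), pmin(rexp(n / 2, 0.05), 365)),
    event = TRUE)
  obs$event <- obs$time < 365
  curves <- suppressMessages(stratify_km(obs))
  expect_setequal(names(curves), c("G2", "G4"))
  grid <- c(30, 90, 180, 300)
  expect_true(all(km_ci_at(curves$G4, grid) > km_ci_at(curves$G2, grid)))
  # single-stratum input equals the pooled curve
  solo <- obs[obs$g_stage == "G4", ]
  pooled <- km_cumulative_incidence(solo$time, solo$event)
  expect_equal(km_ci_at(curves$G4, grid), km_ci_at(pooled, grid))
  # small stratum flagged
  tiny <- rbind(obs, data.frame(patient_id = "x", g_stage = "G5",
                                time = 10, event = TRUE))
  curves <- suppressMessages(stratify_km(tiny))
  expect_true(attr(curves$G5, "small"))
  expect_false(attr(curves$G4, "small"))
})

test_that("conditional variant drops retest-free patients", {
  obs <- data.frame(patient_id = as.character(1:4), g_stage = "G3b",
                    time = c(10, 20, 400, 500),
                    event = c(TRUE, TRUE, FALSE, FALSE))
  un <- suppressMessages(stratify_km(obs))
  co <- suppressMessages(stratify_km(obs, condition_on_retest = TRUE))
  expect_equal(co$G3b$n, 2)
  expect_gt(km_ci_at(co$G3b, 30), km_ci_at(un$G3b, 30))
})
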
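test_that("paw latency averages the two numerically closest trials", {
  expect_equal(paw_latency(c(7.0, 7.4, 9.0)), 7.2)
  expect_equal(paw_latency(c(6.0, 6.0)), 6.0)
  # two pairs tie at gap 1.0; the earliest pair in acquisition order wins
  expect_equal(paw_latency(c(5.0, 6.0, 7.0)), 5.5)
  expect_error(paw_latency(7), "at least 2")
  # exhaustive agreement with a min-gap enumeration oracle
  set.seed(8)
  for (rep in 1:25) {
    v <- round(runif(sample(2:6, 1), 5, 20), 2)
    pairs <- t(combn(length(v), 2))
    gaps <- abs(v[pairs[, 1]] - v[pairs[, 2]])
    best <- pairs[which.min(gaps), ]
    expect_equal(paw_latency(v), mean(v[best]))
  }
})

test_that("session latency averages the per-paw reductions", {
  expect_equal(session_latency(c(10, 10), c(12, 12)), 11)
  expect_equal(session_latency(c(18.7, 18.7), c(18.7, 18.7)), 18.7)
  expect_equal(session_latency(c(7.0, 7.4, 9.0), c(6.0, 6.0)), 6.6)
  expect_error(session_latency(c(10, 10), 12), ">= 2 trials")
})

test_that("ols_slope matches the normal-equations oracle", {
  expect_equal(unname(ols_slope(1:4, c(2, 4, 6, 8))["slope"]), 2)
  expect_equal(unname(ols_slope(1:5, rep(3, 5))["slope"]), 0)
  x <- c(17, 24, 28, 38, 45, 49, 51)
  y <- c(120, 90, 85, 40, 10, -5, -20)
  o <- oracle_slope(x, y)
  expect_equal(unname(ols_slope(x, y)["slope"]), unname(o["slope"]),
               tolerance = 1e-10)
  expect_equal(unname(ols_slope(x, y)["intercept"]), unname(o["intercept"]),
               tolerance = 1e-10)
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    x <- sort(runif(n, 0, 50))
    y <- rnorm(n, 2 * x - 5, 3)
    expect_equal(unname(ols_slope(x, y)["slope"]),
                 unname(oracle_slope(x, y)["slope"]), tolerance = 1e-10)
  }
  expect_error(ols_slope(c(2, 2, 2), 1:3), "distinct")
})

test_that("reflex measures use the first session and the inverted slope", {
  mk <- function(lat_by_session, days = 6:9) {
    do.call(rbind, lapply(seq_along(lat_by_session), function(s)
      data.frame(animal = 1, day = days[s], session = s,
                 paw = rep(c("left", "right"), each = 2),
                 trial_index = rep(1:2, 2),
                 latency_s = lat_by_session[s])))
  }
  tr <- mk(c(18.7, 18.03, 17.37, 16.7))
  expect_equal(basal_reflex_pain(tr), 18.7)
  expect_equal(rate_change_reflex_pain(tr), 0.666, tolerance = 1e-9)
  # input day order must not matter
  shuffled <- tr[rev(seq_len(nrow(tr))), ]
  expect_equal(basal_reflex_pain(shuffled), 18.7)
  expect_equal(rate_change_reflex_pain(shuffled),
               rate_change_reflex_pain(tr))
  # sign conventions: decline -> positive, rise -> negative, flat -> zero
  expect_equal(rate_change_reflex_pain(mk(rep(12, 4))), 0)
  expect_lt(rate_change_reflex_pain(mk(c(10, 12, 14, 16))), 0)
  expect_error(basal_reflex_pain(tr[0, ]), "no sessions")
})

test_that("locomotor measures follow the stated normalizations", {
  cond <- data.frame(
    animal = 1, day = rep(13:16, 2),
    drug = rep(c("VEH", "OXY"), each = 4),
    counts = c(675, 592, 509, 427, 1117, 1138, 1159, 1181)
  )
  expect_equal(basal_loco(cond), 675)
  expect_equal(acute_oxy_loco(cond), 1117 - 675)
  expect_equal(raw_loco_habituation(cond), 82.7, tolerance = 1e-9)
  # normalized series 442, 546, 650, 754: exact linear rise of 104/session
  expect_equal(rate_behavioral_sensitization(cond), 104, tolerance = 1e-9)
  flat <- cond
  flat$counts <- rep(c(500, 900), each = 4)
  expect_equal(rate_behavioral_sensitization(flat), 0)
  expect_equal(raw_loco_habituation(flat), 0)
  expect_error(basal_loco(cond[cond$drug == "OXY", ]), "VEH")
})

test_that("the cohort square-root transform is gated by Shapiro-Wilk", {
  mk_animal <- function(slope) {
    counts <- 700 - slope * (0:3)
    data.frame(animal = 1, day = 13:16, drug = "VEH", counts = counts)
  }
  # strongly right-skewed raw slopes: transform fires, signed root applied
  set.seed(31)
  skewed <- rexp(15, rate = 1 / 60)
  res <- rate_loco_habituation(lapply(skewed, mk_animal))
  expect_true(res$transformed)
  expect_equal(unname(res$values), sign(skewed) * sqrt(abs(skewed)),
               tolerance = 1e-9)
  # near-normal raw slopes: left untouched
  set.seed(32)
  normal <- rnorm(15, 80, 5)
  res2 <- rate_loco_habituation(lapply(normal, mk_animal))
  expect_false(res2$transformed)
  expect_equal(unname(res2$values), normal, tolerance = 1e-9)
  # the signed root is monotone, so cross-animal ordering is preserved
  expect_equal(order(res$values), order(skewed))
  expect_equal(ethopain:::signed_sqrt(0), 0)
  expect_equal(ethopain:::signed_sqrt(-4), -2)
})

test_that("CPP scores implement the three scorings and their identities", {
  mk_test <- function(oxy, veh, center) {
    data.frame(compartment = c("OXY", "VEH", "center"),
               time_s = c(oxy, veh, center))
  }
  pre <- mk_test(400, 500, 300)
  post <- mk_test(500, 400, 300)
  expect_equal(cpp_score(post, pre, "pre_subtraction"), 100)
  expect_equal(cpp_score(post, pre, "veh_subtraction"), 100)
  expect_equal(cpp_score(mk_test(450, 450, 300), method = "veh_subtraction"),
               0)
  expect_equal(cpp_score(mk_test(450, 450, 300), method = "proportion"), 0.5)
  # identity: a test scored against itself is zero preference
  expect_equal(cpp_score(pre, pre, "pre_subtraction"), 0)
  expect_equal(cpp_score(mk_test(393.4, 400, 406.6),
                         mk_test(393.4, 500, 306.6), "pre_subtraction"), 0)
  expect_error(cpp_score(mk_test(0, 0, 1200), method = "proportion"),
               "undefined")
})

test_that("CPP timecourse measures use calendar days as abscissae", {
  days <- c(10, 17, 24, 28, 38, 45, 49, 51)
  oxy <- c(393.4, 513.4, 482.6, 465, 421, 390.2, 372.6, 363.8)  # 120 - 4.4/day
  tests <- do.call(rbind, lapply(seq_along(days), function(i)
    data.frame(animal = 1, day = days[i],
               compartment = c("OXY", "VEH", "center"),
               time_s = c(oxy[i], 1200 - oxy[i] - 400, 400))))
  expect_equal(cpp_at_first_test(tests), 120)
  expect_equal(rate_cpp_extinction(tests), 4.4, tolerance = 1e-9)
  # regression on test index instead of day gives a different slope
  scores <- oxy[-1] - oxy[1]
  by_index <- -unname(ols_slope(seq_along(scores), scores)["slope"])
  expect_gt(abs(by_index - 4.4), 1)
  # constant scores extinguish at rate zero
  const <- tests
  const$time_s[const$compartment == "OXY"] <- 450
  const$time_s[const$compartment == "VEH"] <- 350
  expect_equal(rate_cpp_extinction(const), 0)
})

test_that("post-surgery reflex measures compare paws and baselines", {
  mk <- function(days, left, right) {
    do.call(rbind, lapply(seq_along(days), function(i)
      data.frame(animal = 1, day = days[i],
                 paw = rep(c("left", "right"), each = 2),
                 trial_index = rep(1:2, 2),
                 latency_s = rep(c(left[i], right[i]), each = 2))))
  }
  pre <- mk(6, left = 16, right = 12)
  post <- mk(63:65, left = c(16, 18, 20), right = c(8, 9, 10))
  m <- post_surgery_reflex_measures(pre, post, "right")
  expect_equal(unname(m["surg_paw"]), 9)
  expect_equal(unname(m["surg_vs_nonsurg_pct"]), 50)
  expect_equal(unname(m["delta_surg_paw"]), 9 - 12)
  # symmetric paws give 100%; unchanged latency gives a zero delta
  sym <- mk(63:65, left = c(14, 15, 16), right = c(14, 15, 16))
  ms <- post_surgery_reflex_measures(mk(6, 15, 15), sym, "right")
  expect_equal(unname(ms["surg_vs_nonsurg_pct"]), 100)
  pre0 <- mk(6, 15, 15)
  post0 <- mk(63:65, left = c(15, 15, 15), right = c(15, 15, 15))
  expect_equal(unname(post_surgery_reflex_measures(pre0, post0,
                                                   "right")["delta_surg_paw"]),
               0)
})

test_that("post-surgery CPP deltas subtract the right reference tests", {
  mk_day <- function(day, oxy) data.frame(animal = 1, day = day,
                                          compartment = c("OXY", "VEH", "center"),
                                          time_s = c(oxy, 800 - oxy, 400))
  tests <- rbind(mk_day(10, 393.4), mk_day(17, 493.4), mk_day(51, 300),
                 mk_day(66, 300))
  m <- post_surgery_cpp_measures(tests)
  expect_equal(unname(m["delta_pretest"]), 300 - 393.4)
  expect_equal(unname(m["delta_postcond"]), 300 - 493.4)
  expect_equal(unname(m["delta_presurg"]), 0)
  same <- rbind(mk_day(10, 400), mk_day(17, 400), mk_day(51, 400),
                mk_day(66, 400))
  expect_equal(unname(post_surgery_cpp_measures(same)), c(0, 0, 0))
})

test_that("dose translation scales by body surface area", {
  expect_equal(human_equivalent_dose(0.56, 6.2, 70), 6.3)
  expect_equal(human_equivalent_dose(0, 6.2, 70), 0)
  expect_equal(human_equivalent_dose(6.2, 6.2, 1), 1)
  expect_error(human_equivalent_dose(1, 0, 70), "positive")
})

test_that("the measure table is complete, partial-safe and order-invariant", {
  cfg <- noise_free_config(n_animals = 15L, seed = 44L)
  study <- generate_study(cfg)
  tab <- build_measure_table(study)
  expect_equal(nrow(tab), 15)
  expect_equal(sum(is.na(tab[, -1])), 0)
  expect_named(attr(tab, "transform_flags"))

  # permutation invariance in record order
  study2 <- study
  study2$reflex_trials <- study2$reflex_trials[
    rev(seq_len(nrow(study2$reflex_trials))), ]
  study2$place_tests <- study2$place_tests[
    sample(nrow(study2$place_tests)), ]
  tab2 <- build_measure_table(study2)
  expect_equal(tab2, tab, ignore_attr = TRUE)

  # an animal missing the post-surgery phase keeps its pre-surgery columns
  study3 <- study
  study3$reflex_trials <- study3$reflex_trials[
    !(study3$reflex_trials$animal == 1 & study3$reflex_trials$day >= 56), ]
  tab3 <- build_measure_table(study3)
  expect_false(anyNA(tab3[1, pre_measure_names()]))
  expect_true(all(is.na(tab3[1, c("Reflex pain-surg. paw",
                                  "Reflex pain-delta surg. paw")])))
  expect_error(build_measure_table(list(animals = data.frame())), "empty")
})

test_that("the pipeline inverts a noise-free generator exactly", {
  cfg <- noise_free_config(n_animals = 12L, seed = 77L)
  study <- generate_study(cfg)
  tab <- build_measure_table(study)
  flag <- attr(tab, "transform_flags")[["Rate of loco habituation"]]
  exp_tab <- expected_pre_measures(study$traits, flag)
  for (m in pre_measure_names())
    expect_equal(tab[[m]], exp_tab[[m]], tolerance = 1e-9, label = m)
  # post-surgery: CCI animals show exactly the planted latency reduction
  cci <- study$animals$surgery_arm == "CCI"
  expect_equal(tab[["Reflex pain-delta surg. paw"]][cci],
               rep(-cfg$cci_effect_s, sum(cci)), tolerance = 1e-9)
  expect_equal(tab[["Reflex pain-delta surg. paw"]][!cci],
               rep(0, sum(!cci)), tolerance = 1e-9)
})
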
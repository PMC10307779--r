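#' Canonical measure names
#'
#' Column names of the measure table: eight pre-surgery measures and six
#' post-surgery measures, named as in the outcome-measure summary tables
#' (ASCII rendering: the Greek delta is written `delta`).
#'
#' @return Character vector of measure names.
#' @export
pre_measure_names <- function() {
  c("Basal reflex pain", "Rate of change in reflex pain", "Basal loco",
    "Rate of loco habituation", "Acute OXY loco",
    "Rate of behavioral sensitization", "CPP at first test",
    "Rate of CPP extinction")
}

#' @rdname pre_measure_names
#' @export
post_measure_names <- function() {
  c("Reflex pain-surg. paw", "Reflex pain-surg. paw vs. non-surg. paw",
    "Reflex pain-delta surg. paw", "CPP-delta pre-test CPP",
    "CPP-delta post-cond. CPP", "CPP-delta pre-surg. CPP")
}

#' Per-paw withdrawal latency from repeated trials
#'
#' Two or more latency trials are taken per paw; the two numerically closest
#' values are averaged.  When several pairs tie for the smallest gap, the
#' earliest pair in acquisition order wins, making the reduction
#' deterministic.
#'
#' @param trials Numeric vector of trial latencies in seconds (>= 2 values).
#' @return The mean of the closest pair, in seconds.
#' @export
paw_latency <- function(trials) {
  n <- length(trials)
  if (n < 2L) stop("paw_latency: need at least 2 trials", call. = FALSE)
  if (n == 2L) return(mean(trials))
  best <- c(1L, 2L)
  best_gap <- Inf
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      gap <- abs(trials[i] - trials[j])
      if (gap < best_gap - 1e-12) {
        best_gap <- gap
        best <- c(i, j)
      }
    }
  }
  mean(trials[best])
}

#' Session-level withdrawal latency
#'
#' Mean of the two per-paw [paw_latency()] values for one reflex session.
#'
#' @param left,right Numeric trial vectors for the two paws.
#' @return Session latency in seconds.
#' @export
session_latency <- function(left, right) {
  if (length(left) < 2L || length(right) < 2L)
    stop("session_latency: both paws need >= 2 trials", call. = FALSE)
  (paw_latency(left) + paw_latency(right)) / 2
}

#' Ordinary least-squares slope and intercept
#'
#' @param x Ordered abscissae (at least two distinct values).
#' @param y Responses, same length as `x`.
#' @return Named numeric vector `c(slope =, intercept =)`.
#' @export
ols_slope <- function(x, y) {
  if (length(x) != length(y)) stop("ols_slope: unequal lengths", call. = FALSE)
  if (length(x) < 2L || length(unique(x)) < 2L)
    stop("ols_slope: need >= 2 distinct x values", call. = FALSE)
  xc <- x - mean(x)
  slope <- sum(xc * (y - mean(y))) / sum(xc^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# per-session latencies for one animal, sorted by day
session_latencies <- function(trials) {
  trials <- trials[order(trials$day, trials$trial_index), , drop = FALSE]
  days <- sort(unique(trials$day))
  vapply(days, function(d) {
    td <- trials[trials$day == d, , drop = FALSE]
    paws <- split(td$latency_s, td$paw)
    if (length(paws) < 2L)
      stop("session on day ", d, ": both paws required", call. = FALSE)
    session_latency(paws[[1]], paws[[2]])
  }, numeric(1)) -> lat
  names(lat) <- days
  lat
}

#' Basal reflex pain
#'
#' Withdrawal latency averaged across both paws in the earliest pre-surgery
#' reflex session.  Input day order is irrelevant; sessions are sorted by
#' study day first.
#'
#' @param trials Data.frame of one animal's pre-surgery reflex trials
#'   (columns day, paw, trial_index, latency_s).
#' @return Latency in seconds.
#' @export
basal_reflex_pain <- function(trials) {
  if (!nrow(trials)) stop("basal_reflex_pain: no sessions", call. = FALSE)
  unname(session_latencies(trials)[1])
}

#' Rate of change in reflex pain
#'
#' Inverted OLS slope of session-mean withdrawal latency over session index;
#' positive values mean latencies declined (sensitization to the thermal
#' stimulus), negative values mean habituation.
#'
#' @inheritParams basal_reflex_pain
#' @return Slope in s/session (inverted).
#' @export
rate_change_reflex_pain <- function(trials) {
  lat <- session_latencies(trials)
  if (length(lat) < 2L)
    stop("rate_change_reflex_pain: need >= 2 sessions", call. = FALSE)
  -unname(ols_slope(seq_along(lat), lat)["slope"])
}

#' Basal locomotion
#'
#' Absolute beam-break counts following vehicle administration on the first
#' conditioning day.
#'
#' @param cond Data.frame of one animal's conditioning records (columns day,
#'   drug, counts).
#' @return Counts.
#' @export
basal_loco <- function(cond) {
  veh <- cond[cond$drug == "VEH", , drop = FALSE]
  if (!nrow(veh)) stop("basal_loco: no VEH sessions", call. = FALSE)
  veh$counts[which.min(veh$day)]
}

#' Raw locomotor-habituation slope for one animal
#'
#' Inverted OLS slope of vehicle-session beam-break counts over session
#' index (positive = habituation).  The cohort-level square-root transform
#' is applied in [rate_loco_habituation()].
#'
#' @inheritParams basal_loco
#' @return Inverted slope in counts/session.
#' @export
raw_loco_habituation <- function(cond) {
  veh <- cond[cond$drug == "VEH", , drop = FALSE]
  if (nrow(veh) < 2L)
    stop("raw_loco_habituation: need >= 2 VEH sessions", call. = FALSE)
  veh <- veh[order(veh$day), , drop = FALSE]
  -unname(ols_slope(seq_len(nrow(veh)), veh$counts)["slope"])
}

# signed square root, the monotone generalization used when raw slopes can
# be negative
signed_sqrt <- function(x) sign(x) * sqrt(abs(x))

#' Rate of locomotor habituation across a cohort
#'
#' Computes each animal's raw inverted vehicle-locomotion slope, then tests
#' the cohort of raw slopes for normality (Shapiro-Wilk).  If normality is
#' rejected at p < 0.05 the signed square root is applied to every animal
#' and the transform flag is set; otherwise raw slopes are returned
#' unchanged.  Applied to all animals or none, so the column stays on one
#' scale.
#'
#' @param cond_by_animal Named list of per-animal conditioning data.frames.
#' @param transform One of `"auto"` (Shapiro-Wilk rule), `"always"`,
#'   `"never"`.
#' @return List with `values` (named per animal) and `transformed` (logical
#'   flag).
#' @export
rate_loco_habituation <- function(cond_by_animal, transform = "auto") {
  raw <- vapply(cond_by_animal, raw_loco_habituation, numeric(1))
  transform <- match.arg(transform, c("auto", "always", "never"))
  apply_tf <- switch(transform,
    always = TRUE,
    never = FALSE,
    auto = length(raw) >= 3L && stats::sd(raw) > 0 &&
      stats::shapiro.test(raw)$p.value < 0.05
  )
  list(values = if (apply_tf) signed_sqrt(raw) else raw,
       transformed = apply_tf)
}

#' Acute oxycodone-stimulated locomotion
#'
#' First-day oxycodone beam-break counts normalized by subtracting the
#' same-day vehicle counts; may be negative.
#'
#' @inheritParams basal_loco
#' @return Counts (OXY - VEH on the first conditioning day).
#' @export
acute_oxy_loco <- function(cond) {
  d1 <- min(cond$day)
  oxy <- cond$counts[cond$drug == "OXY" & cond$day == d1]
  veh <- cond$counts[cond$drug == "VEH" & cond$day == d1]
  if (!length(oxy) || !length(veh))
    stop("acute_oxy_loco: first-day OXY and VEH sessions required",
         call. = FALSE)
  oxy - veh
}

#' Rate of behavioral sensitization
#'
#' OLS slope (not inverted) of vehicle-normalized oxycodone locomotion over
#' the conditioning sessions; positive values mean locomotor sensitization.
#'
#' @inheritParams basal_loco
#' @return Slope in counts/session.
#' @export
rate_behavioral_sensitization <- function(cond) {
  days <- sort(unique(cond$day))
  norm <- vapply(days, function(d) {
    oxy <- cond$counts[cond$drug == "OXY" & cond$day == d]
    veh <- cond$counts[cond$drug == "VEH" & cond$day == d]
    if (!length(oxy) || !length(veh))
      stop("rate_behavioral_sensitization: unpaired day ", d, call. = FALSE)
    oxy - veh
  }, numeric(1))
  if (length(norm) < 2L)
    stop("rate_behavioral_sensitization: need >= 2 paired days",
         call. = FALSE)
  unname(ols_slope(seq_along(norm), norm)["slope"])
}

oxy_time <- function(tests, day) {
  t <- tests$time_s[tests$day == day & tests$compartment == "OXY"]
  if (!length(t)) stop("no place test on day ", day, call. = FALSE)
  t
}

#' Conditioned place preference score
#'
#' Three scorings are supported: `pre_subtraction` (drug-paired compartment
#' time minus the pre-test drug-paired time; the primary scoring),
#' `veh_subtraction` (drug-paired minus vehicle-paired time within the same
#' test) and `proportion` (drug-paired time over the summed time in both
#' conditioning compartments, center excluded).
#'
#' @param test,pretest One-test data.frames (columns compartment, time_s).
#'   `pretest` is only consulted for `pre_subtraction`.
#' @param method Scoring method.
#' @return Score in seconds (`pre_subtraction`, `veh_subtraction`) or a
#'   proportion in \[0, 1\].
#' @export
cpp_score <- function(test, pretest = NULL,
                      method = c("pre_subtraction", "veh_subtraction",
                                 "proportion")) {
  method <- match.arg(method)
  g <- function(df, comp) {
    t <- df$time_s[df$compartment == comp]
    if (!length(t)) stop("cpp_score: missing compartment ", comp, call. = FALSE)
    t
  }
  switch(method,
    pre_subtraction = {
      if (is.null(pretest))
        stop("cpp_score: pre_subtraction needs a pretest", call. = FALSE)
      g(test, "OXY") - g(pretest, "OXY")
    },
    veh_subtraction = g(test, "OXY") - g(test, "VEH"),
    proportion = {
      denom <- g(test, "OXY") + g(test, "VEH")
      if (denom <= 0)
        stop("cpp_score: proportion undefined when OXY + VEH time is 0",
             call. = FALSE)
      g(test, "OXY") / denom
    }
  )
}

#' CPP at first test
#'
#' Pre-test-subtracted drug-paired compartment time at the first
#' post-conditioning test.
#'
#' @param tests One animal's place tests (columns day, compartment, time_s).
#' @param pretest_day,first_test_day Study days of the pre-test and first
#'   post-conditioning test.
#' @return Score in seconds.
#' @export
cpp_at_first_test <- function(tests, pretest_day = 10, first_test_day = 17) {
  oxy_time(tests, first_test_day) - oxy_time(tests, pretest_day)
}

#' Rate of CPP extinction
#'
#' Inverted OLS slope of pre-test-subtracted CPP scores over the actual
#' study-day numbers of the post-conditioning tests (calendar days, not test
#' indices, so the unit is s/day); positive values mean extinction.
#'
#' @inheritParams cpp_at_first_test
#' @param test_days Study days of the post-conditioning tests to include.
#' @return Slope in s/day (inverted).
#' @export
rate_cpp_extinction <- function(tests, pretest_day = 10,
                                test_days = c(17, 24, 28, 38, 45, 49, 51)) {
  pre <- oxy_time(tests, pretest_day)
  scores <- vapply(test_days, function(d) oxy_time(tests, d) - pre, numeric(1))
  if (length(scores) < 2L)
    stop("rate_cpp_extinction: need >= 2 post-conditioning tests",
         call. = FALSE)
  -unname(ols_slope(test_days, scores)["slope"])
}

#' Post-surgery reflex-pain measures
#'
#' From the three post-surgery reflex sessions and the first pre-surgery
#' session: (a) mean surgeried-paw withdrawal latency across the three
#' post-surgery sessions, (b) that mean expressed as a percentage of the
#' mean non-surgeried-paw latency over the same sessions, and (c) the change
#' of (a) from the surgeried paw's latency in the first pre-surgery session
#' (negative = sensitized by the surgery).
#'
#' @param pre_trials First pre-surgery session trials (both paws).
#' @param post_trials All post-surgery reflex trials (both paws, 3 sessions).
#' @param surgery_paw `"left"` or `"right"`.
#' @return Named numeric vector with elements `surg_paw` (s),
#'   `surg_vs_nonsurg_pct` (%), `delta_surg_paw` (s).
#' @export
post_surgery_reflex_measures <- function(pre_trials, post_trials,
                                         surgery_paw) {
  stopifnot(surgery_paw %in% c("left", "right"))
  other <- setdiff(c("left", "right"), surgery_paw)
  per_paw <- function(trials, paw) {
    days <- sort(unique(trials$day))
    vapply(days, function(d) {
      v <- trials$latency_s[trials$day == d & trials$paw == paw]
      if (length(v) < 2L)
        stop("post_surgery_reflex_measures: paw ", paw, " missing on day ",
             d, call. = FALSE)
      paw_latency(v[order(trials$trial_index[trials$day == d &
                                               trials$paw == paw])])
    }, numeric(1))
  }
  surg <- mean(per_paw(post_trials, surgery_paw))
  nonsurg <- mean(per_paw(post_trials, other))
  pre_day <- min(pre_trials$day)
  pre_surg <- per_paw(pre_trials[pre_trials$day == pre_day, , drop = FALSE],
                      surgery_paw)
  c(surg_paw = surg,
    surg_vs_nonsurg_pct = 100 * surg / nonsurg,
    delta_surg_paw = surg - unname(pre_surg))
}

#' Post-surgery CPP measures
#'
#' Drug-paired compartment time at the post-surgery test minus, in turn,
#' the pre-test time, the first post-conditioning test time, and the final
#' extinction-test time.
#'
#' @inheritParams cpp_at_first_test
#' @param last_ext_day Day of the final pre-surgery extinction test.
#' @param post_day Day of the post-surgery test.
#' @return Named numeric vector `delta_pretest`, `delta_postcond`,
#'   `delta_presurg`, in seconds.
#' @export
post_surgery_cpp_measures <- function(tests, pretest_day = 10,
                                      first_test_day = 17, last_ext_day = 51,
                                      post_day = 66) {
  post <- oxy_time(tests, post_day)
  c(delta_pretest = post - oxy_time(tests, pretest_day),
    delta_postcond = post - oxy_time(tests, first_test_day),
    delta_presurg = post - oxy_time(tests, last_ext_day))
}

#' Human-equivalent dose by body-surface-area scaling
#'
#' Converts an animal dose (mg/kg) to the equivalent absolute dose for a
#' reference human using the species conversion divisor (6.2 for rat).
#'
#' @param animal_dose_mg_kg Animal dose in mg/kg.
#' @param divisor Species conversion divisor (> 0).
#' @param human_mass_kg Reference human body mass in kg (> 0).
#' @return Dose in mg, rounded to one decimal place.
#' @export
human_equivalent_dose <- function(animal_dose_mg_kg, divisor = 6.2,
                                  human_mass_kg = 70) {
  if (divisor <= 0 || human_mass_kg <= 0)
    stop("human_equivalent_dose: divisor and mass must be positive",
         call. = FALSE)
  round(animal_dose_mg_kg / divisor * human_mass_kg, 1)
}

#' Build the animals-by-measures table
#'
#' Derives every outcome measure available for each animal: the eight
#' pre-surgery measures and the six post-surgery measures.  Animals missing
#' a phase get `NA` in that phase's columns only; nothing is imputed.  The
#' result is invariant to animal and record order in the input.
#'
#' @param study A `study_dataset` (from [generate_study()] or
#'   [read_study()]).
#' @param sqrt_transform Transform policy for the locomotor-habituation
#'   column, passed to [rate_loco_habituation()].
#' @return A data.frame, one row per animal, with measure columns named as
#'   [pre_measure_names()] and [post_measure_names()]; attribute
#'   `transform_flags` records which columns were transformed.
#' @export
build_measure_table <- function(study, sqrt_transform = "auto") {
  animals <- study$animals
  if (is.null(animals) || !nrow(animals))
    stop("build_measure_table: empty dataset", call. = FALSE)
  ids <- sort(unique(animals$animal))
  cfg <- study$config
  pretest_day <- if (!is.null(cfg)) cfg$pretest_day else 10
  test_days <- if (!is.null(cfg)) cfg$cpp_test_days else c(17, 24, 28, 38, 45, 49, 51)
  post_day <- if (!is.null(cfg)) cfg$post_test_day else 66
  pre_cut <- 56  # surgery happens days 56-57; reflex days before this are pre-surgery

  rt <- study$reflex_trials
  cd <- study$conditioning
  pt <- study$place_tests

  tab <- data.frame(animal = ids, check.names = FALSE)
  for (m in c(pre_measure_names(), post_measure_names())) tab[[m]] <- NA_real_

  try_measure <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  cond_by_animal <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    pre_rt <- rt[rt$animal == id & rt$day < pre_cut, , drop = FALSE]
    post_rt <- rt[rt$animal == id & rt$day >= pre_cut, , drop = FALSE]
    cdi <- cd[cd$animal == id, , drop = FALSE]
    pti <- pt[pt$animal == id, , drop = FALSE]

    if (nrow(pre_rt)) {
      tab[i, "Basal reflex pain"] <- try_measure(basal_reflex_pain(pre_rt))
      tab[i, "Rate of change in reflex pain"] <-
        try_measure(rate_change_reflex_pain(pre_rt))
    }
    if (nrow(cdi)) {
      tab[i, "Basal loco"] <- try_measure(basal_loco(cdi))
      tab[i, "Acute OXY loco"] <- try_measure(acute_oxy_loco(cdi))
      tab[i, "Rate of behavioral sensitization"] <-
        try_measure(rate_behavioral_sensitization(cdi))
      cond_by_animal[[as.character(id)]] <- cdi
    }
    if (nrow(pti)) {
      tab[i, "CPP at first test"] <-
        try_measure(cpp_at_first_test(pti, pretest_day, test_days[1]))
      tab[i, "Rate of CPP extinction"] <-
        try_measure(rate_cpp_extinction(pti, pretest_day, test_days))
      if (post_day %in% pti$day) {
        ps <- try_measure(post_surgery_cpp_measures(
          pti, pretest_day, test_days[1], test_days[length(test_days)],
          post_day))
        if (!all(is.na(ps))) {
          tab[i, "CPP-delta pre-test CPP"] <- ps[["delta_pretest"]]
          tab[i, "CPP-delta post-cond. CPP"] <- ps[["delta_postcond"]]
          tab[i, "CPP-delta pre-surg. CPP"] <- ps[["delta_presurg"]]
        }
      }
    }
    if (nrow(post_rt) && nrow(pre_rt)) {
      paw <- animals$surgery_paw[animals$animal == id][1]
      if (is.null(paw) || is.na(paw)) paw <- "right"
      pre1 <- pre_rt[pre_rt$day == min(pre_rt$day), , drop = FALSE]
      pm <- try_measure(post_surgery_reflex_measures(pre1, post_rt, paw))
      if (!all(is.na(pm))) {
        tab[i, "Reflex pain-surg. paw"] <- pm[["surg_paw"]]
        tab[i, "Reflex pain-surg. paw vs. non-surg. paw"] <-
          pm[["surg_vs_nonsurg_pct"]]
        tab[i, "Reflex pain-delta surg. paw"] <- pm[["delta_surg_paw"]]
      }
    }
  }

  hab_flag <- FALSE
  if (length(cond_by_animal)) {
    hab <- tryCatch(rate_loco_habituation(cond_by_animal, sqrt_transform),
                    error = function(e) NULL)
    if (!is.null(hab)) {
      idx <- match(as.numeric(names(hab$values)), tab$animal)
      tab[idx, "Rate of loco habituation"] <- unname(hab$values)
      hab_flag <- hab$transformed
    }
  }

  flags <- stats::setNames(
    rep(FALSE, length(c(pre_measure_names(), post_measure_names()))),
    c(pre_measure_names(), post_measure_names()))
  flags["Rate of loco habituation"] <- hab_flag
  attr(tab, "transform_flags") <- flags
  tab
}
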
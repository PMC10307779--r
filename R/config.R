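#' Latent trait names used by the cohort generator
#'
#' Eight per-animal latent traits, each expressed in the units of the
#' behavioral measure it drives downstream: basal hindpaw withdrawal latency
#' (s), per-session latency decline (s/session), basal beam-break locomotion
#' (counts), locomotor habituation (square-root scale, so the planted decline
#' in counts/session is its square), acute drug-induced locomotor boost
#' (counts), locomotor sensitization slope (counts/session), conditioned
#' place preference strength (s), and CPP extinction rate (s/day).
#'
#' @return Character vector of the eight trait names, in canonical order.
#' @export
trait_names <- function() {
  c("basal_latency", "latency_decline", "basal_loco", "loco_habituation",
    "oxy_loco_boost", "sensitization_slope", "cpp_strength", "extinction_rate")
}

#' Default latent correlation structure for the synthetic cohort
#'
#' Embeds the headline associations of the study the generator emulates:
#' a strong negative correlation (-0.7) between basal withdrawal latency and
#' locomotor sensitization, a positive correlation between basal locomotion
#' and locomotor habituation, a positive correlation between sensitization
#' and CPP extinction rate, and a negative correlation between the rate of
#' change in reflex latency and basal locomotion.  All remaining pairs are
#' uncorrelated.  The matrix is positive definite by construction (smallest
#' eigenvalue approximately 0.25).
#'
#' @return An 8 x 8 symmetric correlation matrix with named dimnames.
#' @export
default_latent_corr <- function() {
  tr <- trait_names()
  R <- diag(length(tr))
  dimnames(R) <- list(tr, tr)
  set2 <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set2("basal_latency", "sensitization_slope", -0.70)
  set2("basal_latency", "extinction_rate", -0.45)
  set2("sensitization_slope", "extinction_rate", 0.60)
  set2("basal_loco", "loco_habituation", 0.60)
  set2("latency_decline", "basal_loco", -0.55)
  set2("latency_decline", "loco_habituation", -0.35)
  set2("basal_loco", "oxy_loco_boost", 0.45)
  set2("loco_habituation", "oxy_loco_boost", 0.35)
  set2("cpp_strength", "extinction_rate", 0.30)
  R
}

#' Build a cohort generator configuration
#'
#' Study-phase geometry follows the five-phase design: four pre-surgery
#' reflex sessions (days 6-9), a place-preference pre-test (day 10), four
#' conditioning days with paired vehicle and oxycodone sessions (days
#' 13-16), seven drug-free place tests (days 17, 24, 28, 38, 45, 49, 51),
#' sham/CCI surgery, three post-surgery reflex sessions (days 63-65) and a
#' final place test (day 66).  Trait means default to the reported group
#' means (e.g. 18.7 s basal latency, 675 counts basal locomotion, 4.4 s/day
#' extinction rate); trait SDs are the between-animal SDs implied by the
#' reported SEMs at n = 15.
#'
#' @param n_animals Cohort size (>= 3).
#' @param seed Integer seed; one global seed drives per-animal, per-phase
#'   substreams so adding animals does not perturb existing animals' data.
#' @param latent_corr Symmetric positive-semidefinite correlation matrix over
#'   the eight latent traits (unit diagonal, entries in \[-1, 1\]).
#' @param trait_means,trait_sds Named numeric vectors over [trait_names()].
#' @param trial_noise_sd Per-trial latency noise SD, seconds.
#' @param count_dispersion Negative-binomial overdispersion of beam-break
#'   counts (variance = mu + dispersion * mu^2); 0 means deterministic
#'   expected counts.
#' @param cpp_noise_sd Per-test noise SD on compartment time, seconds.
#' @param test_length_s Place-test length, seconds (default 1200 = 20 min).
#' @param n_reflex_sessions Number of pre-surgery reflex sessions.
#' @param n_trials_per_paw Withdrawal-latency trials per paw per session
#'   (>= 2; the two numerically closest are averaged downstream).
#' @param conditioning_days Number of conditioning days.
#' @param cpp_test_days Study-day numbers of the post-conditioning tests.
#' @param cci_effect_s Latency reduction (s) of the surgeried paw in CCI
#'   animals.
#' @param center_drift_s_per_test Linear trend in center-compartment time
#'   per test, seconds, emulating the drift toward the neutral compartment.
#' @param pretest_oxy_s,pretest_center_s Cohort baseline pre-test times in
#'   the to-be-drug-paired and center compartments.
#' @return A validated object of class `generator_config`.
#' @export
generator_config <- function(n_animals = 15L,
                             seed = 20230628L,
                             latent_corr = default_latent_corr(),
                             trait_means = c(basal_latency = 18.7,
                                             latency_decline = 0.667,
                                             basal_loco = 675,
                                             loco_habituation = 8.7,
                                             oxy_loco_boost = 442,
                                             sensitization_slope = 104,
                                             cpp_strength = 120,
                                             extinction_rate = 4.4),
                             trait_sds = c(basal_latency = 1.2,
                                           latency_decline = 0.75,
                                           basal_loco = 218,
                                           loco_habituation = 2.6,
                                           oxy_loco_boost = 594,
                                           sensitization_slope = 168,
                                           cpp_strength = 153,
                                           extinction_rate = 3.5),
                             trial_noise_sd = 0.5,
                             count_dispersion = 0.002,
                             cpp_noise_sd = 30,
                             test_length_s = 1200,
                             n_reflex_sessions = 4L,
                             n_trials_per_paw = 3L,
                             conditioning_days = 4L,
                             cpp_test_days = c(17L, 24L, 28L, 38L, 45L, 49L, 51L),
                             cci_effect_s = 8,
                             center_drift_s_per_test = 10,
                             pretest_oxy_s = 393.4,
                             pretest_center_s = 413.2) {
  cfg <- structure(list(
    n_animals = as.integer(n_animals),
    seed = as.integer(seed),
    latent_corr = latent_corr,
    trait_means = trait_means,
    trait_sds = trait_sds,
    trial_noise_sd = trial_noise_sd,
    count_dispersion = count_dispersion,
    cpp_noise_sd = cpp_noise_sd,
    test_length_s = test_length_s,
    n_reflex_sessions = as.integer(n_reflex_sessions),
    n_trials_per_paw = as.integer(n_trials_per_paw),
    conditioning_days = as.integer(conditioning_days),
    reflex_days = 6L + seq_len(as.integer(n_reflex_sessions)) - 1L,
    pretest_day = 10L,
    conditioning_day_numbers = 13L + seq_len(as.integer(conditioning_days)) - 1L,
    cpp_test_days = as.integer(cpp_test_days),
    post_reflex_days = c(63L, 64L, 65L),
    post_test_day = 66L,
    cci_effect_s = cci_effect_s,
    center_drift_s_per_test = center_drift_s_per_test,
    pretest_oxy_s = pretest_oxy_s,
    pretest_center_s = pretest_center_s,
    latency_min_s = 5,
    latency_max_s = 20
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' @rdname generator_config
#' @export
default_config <- function() generator_config()

#' Validate a generator configuration
#'
#' Checks the structural invariants: the latent correlation matrix is
#' symmetric, unit-diagonal, has entries in \[-1, 1\] and is positive
#' semidefinite (to numerical tolerance); the cohort has at least three
#' animals; all scale parameters are non-negative and the test length is
#' positive.
#'
#' @param cfg A `generator_config`.
#' @return `cfg`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  tr <- trait_names()
  R <- cfg$latent_corr
  if (!is.matrix(R) || !identical(dim(R), c(8L, 8L)))
    stop("latent_corr must be an 8 x 8 matrix over the latent traits",
         call. = FALSE)
  if (is.null(dimnames(R))) dimnames(R) <- list(tr, tr)
  if (!identical(rownames(R), tr) || !identical(colnames(R), tr))
    stop("latent_corr dimnames must match trait_names()", call. = FALSE)
  if (max(abs(R - t(R))) > 1e-8)
    stop("latent_corr must be symmetric", call. = FALSE)
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop("latent_corr must have a unit diagonal", call. = FALSE)
  if (any(R < -1 - 1e-8) || any(R > 1 + 1e-8))
    stop("latent_corr entries must lie in [-1, 1]", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("latent_corr is not positive semidefinite (smallest eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  if (is.na(cfg$n_animals) || cfg$n_animals < 3L)
    stop("n_animals must be at least 3", call. = FALSE)
  if (!identical(sort(names(cfg$trait_means)), sort(tr)) ||
      !identical(sort(names(cfg$trait_sds)), sort(tr)))
    stop("trait_means and trait_sds must be named over trait_names()",
         call. = FALSE)
  scales <- c(cfg$trait_sds, cfg$trial_noise_sd, cfg$count_dispersion,
              cfg$cpp_noise_sd)
  if (any(scales < 0))
    stop("all scale parameters must be >= 0", call. = FALSE)
  if (cfg$test_length_s <= 0)
    stop("test_length_s must be positive", call. = FALSE)
  if (cfg$n_trials_per_paw < 2L)
    stop("n_trials_per_paw must be at least 2", call. = FALSE)
  invisible(cfg)
}

# Deterministic per-animal, per-phase substream: mixes the global seed with
# the animal index and a phase code so regenerating with more animals leaves
# earlier animals' records untouched.  Kept strictly below 2^31 - 1.
phase_seed <- function(seed, animal, phase_code) {
  (as.double(seed) %% 1000000007 + 1000003 * as.double(animal) +
     10007 * as.double(phase_code)) %% 2147483647
}

# Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG
# state afterwards so the generator never perturbs the global stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
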
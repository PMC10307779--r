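#' Sample per-animal latent traits
#'
#' Draws one row per animal from a multivariate normal with the configured
#' means, SDs and correlation structure, via a symmetric eigendecomposition
#' factor of the correlation matrix (so exactly positive-semidefinite,
#' possibly singular, matrices are handled).  Output is identical for
#' identical seeds and unaffected by, and not affecting, the caller's RNG
#' state.
#'
#' @param cfg A [generator_config()].
#' @return A data.frame with column `animal` and one column per latent
#'   trait, `n_animals` rows.
#' @export
sample_latent_traits <- function(cfg) {
  validate_generator_config(cfg)
  tr <- trait_names()
  ed <- eigen(cfg$latent_corr, symmetric = TRUE)
  if (min(ed$values) < -1e-8)
    stop("latent_corr is not positive semidefinite", call. = FALSE)
  L <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0))) %*% t(ed$vectors)
  n <- cfg$n_animals
  # per-animal substream: each animal draws its own 8 standard normals
  Z <- t(vapply(seq_len(n), function(i) {
    with_local_seed(phase_seed(cfg$seed, i, 0L), stats::rnorm(length(tr)))
  }, numeric(length(tr))))
  X <- Z %*% t(L)
  X <- sweep(X, 2L, cfg$trait_sds[tr], "*")
  X <- sweep(X, 2L, cfg$trait_means[tr], "+")
  colnames(X) <- tr
  data.frame(animal = seq_len(n), X, check.names = FALSE)
}

# Negative-binomial count with variance mu + dispersion * mu^2; dispersion 0
# returns the (real-valued) expectation so noise-free runs are exactly
# invertible by the measure pipeline.
nb_count <- function(n, mu, dispersion) {
  mu <- pmax(mu, 0)
  if (dispersion <= 0) return(mu)
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

clip_latency <- function(x, cfg) pmin(pmax(x, cfg$latency_min_s), cfg$latency_max_s)

# Compartment-time triple for one place test: clip negatives then rescale
# proportionally so times always compose to the test length.
compose_test <- function(oxy, veh, center, total) {
  v <- pmax(c(oxy, veh, center), 0)
  s <- sum(v)
  if (s <= 0) v <- c(total / 3, total / 3, total / 3) else v <- v * total / s
  v
}

#' Generate a full synthetic study cohort
#'
#' Produces session-level records for every phase of the five-phase design:
#' pre-surgery reflex sessions (per-trial withdrawal latencies, both paws,
#' clipped to the apparatus range \[5, 20\] s before any averaging), paired
#' vehicle/oxycodone conditioning sessions (negative-binomial beam-break
#' counts; vehicle habituates by the squared habituation trait per session,
#' oxycodone adds the acute boost plus the sensitization slope), a pre-test
#' and repeated place tests (drug-paired compartment time rises by the CPP
#' strength then declines with the extinction rate; center time drifts
#' upward; triples renormalized to the test length), a balanced sham/CCI
#' surgery assignment, three post-surgery reflex sessions (surgeried paw
#' reduced by `cci_effect_s` in CCI animals only) and one post-surgery place
#' test.
#'
#' @param cfg A [generator_config()].
#' @param traits Optional pre-sampled latent traits (as from
#'   [sample_latent_traits()]); sampled from `cfg` when `NULL`.
#' @return An object of class `study_dataset`: a list of data.frames
#'   `animals`, `reflex_trials`, `conditioning`, `place_tests`, plus the
#'   generating `config` and `traits`.
#' @export
generate_study <- function(cfg, traits = NULL) {
  validate_generator_config(cfg)
  if (is.null(traits)) traits <- sample_latent_traits(cfg)
  n <- cfg$n_animals
  ntr <- cfg$n_trials_per_paw

  # balanced surgery arms: alternating by animal index with a seed-derived
  # phase, so arms stay balanced (to within one) and an animal's assignment
  # is stable when the cohort is extended
  start <- with_local_seed(phase_seed(cfg$seed, 0L, 9L), sample(0:1, 1))
  arms <- ifelse((seq_len(n) + start) %% 2 == 0, "sham", "CCI")
  sexes <- rep_len(c("F", "M"), n)
  animals <- data.frame(animal = seq_len(n), sex = sexes, surgery_arm = arms,
                        surgery_paw = "right", stringsAsFactors = FALSE)

  reflex <- vector("list", n)
  cond <- vector("list", n)
  place <- vector("list", n)

  # grid helper: trials within paw within session, a fixed draw order
  reflex_grid <- function(days, sessions) {
    ns <- length(days)
    data.frame(
      day = rep(days, each = 2L * ntr),
      session = rep(sessions, each = 2L * ntr),
      paw = rep(rep(c("left", "right"), each = ntr), times = ns),
      trial_index = rep(seq_len(ntr), times = 2L * ns)
    )
  }

  for (i in seq_len(n)) {
    ti <- traits[traits$animal == i, , drop = FALSE]

    # -- phase 1: pre-surgery reflex testing -------------------------------
    pre <- with_local_seed(phase_seed(cfg$seed, i, 1L), {
      g <- reflex_grid(cfg$reflex_days, seq_len(cfg$n_reflex_sessions))
      mu <- ti$basal_latency - ti$latency_decline * (g$session - 1)
      lat <- clip_latency(mu + stats::rnorm(nrow(g), 0, cfg$trial_noise_sd),
                          cfg)
      data.frame(animal = i, g[1:2], paw = g$paw,
                 trial_index = g$trial_index, latency_s = lat)
    })

    # -- phase 2: conditioning locomotion ---------------------------------
    cd <- with_local_seed(phase_seed(cfg$seed, i, 2L), {
      idx <- seq_len(cfg$conditioning_days)
      mu_veh <- pmax(ti$basal_loco - ti$loco_habituation^2 * (idx - 1), 0)
      mu_oxy <- pmax(mu_veh + ti$oxy_loco_boost +
                       ti$sensitization_slope * (idx - 1), 0)
      rbind(
        data.frame(animal = i, day = cfg$conditioning_day_numbers, drug = "VEH",
                   counts = nb_count(length(idx), mu_veh, cfg$count_dispersion)),
        data.frame(animal = i, day = cfg$conditioning_day_numbers, drug = "OXY",
                   counts = nb_count(length(idx), mu_oxy, cfg$count_dispersion))
      )
    })

    # -- phases 2/3/5: pre-test, place tests, post-surgery test -----------
    pt <- with_local_seed(phase_seed(cfg$seed, i, 3L), {
      days <- c(cfg$pretest_day, cfg$cpp_test_days, cfg$post_test_day)
      j <- seq_along(days) - 1L
      noise <- c(0, stats::rnorm(length(days) - 1L, 0, cfg$cpp_noise_sd))
      oxy <- ifelse(j == 0L, cfg$pretest_oxy_s,
                    cfg$pretest_oxy_s + ti$cpp_strength -
                      ti$extinction_rate * (days - cfg$cpp_test_days[1]) +
                      noise)
      center <- cfg$pretest_center_s + cfg$center_drift_s_per_test * j
      veh <- cfg$test_length_s - oxy - center
      triples <- mapply(compose_test, oxy, veh, center,
                        MoreArgs = list(total = cfg$test_length_s))
      data.frame(animal = i, day = rep(days, each = 3L),
                 compartment = rep(c("OXY", "VEH", "center"), length(days)),
                 time_s = as.vector(triples))
    })

    # -- phase 4: post-surgery reflex testing -----------------------------
    post <- with_local_seed(phase_seed(cfg$seed, i, 4L), {
      cci <- animals$surgery_arm[i] == "CCI"
      ns0 <- length(cfg$post_reflex_days)
      g <- reflex_grid(cfg$post_reflex_days,
                       cfg$n_reflex_sessions + seq_len(ns0))
      mu <- ti$basal_latency -
        ifelse(cci & g$paw == animals$surgery_paw[i], cfg$cci_effect_s, 0)
      lat <- clip_latency(mu + stats::rnorm(nrow(g), 0, cfg$trial_noise_sd),
                          cfg)
      data.frame(animal = i, g[1:2], paw = g$paw,
                 trial_index = g$trial_index, latency_s = lat)
    })

    reflex[[i]] <- rbind(pre, post)
    cond[[i]] <- cd
    place[[i]] <- pt
  }

  structure(list(
    animals = animals,
    reflex_trials = do.call(rbind, reflex),
    conditioning = do.call(rbind, cond),
    place_tests = do.call(rbind, place),
    config = cfg,
    traits = traits
  ), class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Synthetic behavioral study dataset\n")
  cat("  animals:          ", nrow(x$animals), " (",
      sum(x$animals$surgery_arm == "CCI"), " CCI / ",
      sum(x$animals$surgery_arm == "sham"), " sham)\n", sep = "")
  cat("  reflex trials:    ", nrow(x$reflex_trials), "\n", sep = "")
  cat("  conditioning rows:", nrow(x$conditioning), "\n")
  cat("  place-test rows:  ", nrow(x$place_tests), "\n", sep = "")
  invisible(x)
}

#' Validate a study dataset against the session-level invariants
#'
#' Rejects any record violating the apparatus constraints before measures
#' are computed: withdrawal latencies outside \[5, 20\] s, negative
#' beam-break counts, unpaired conditioning days, or place tests whose
#' compartment times fail to compose to the test length.  Errors name the
#' offending table, row and column.
#'
#' @param study A `study_dataset` (or a like-shaped list of data.frames).
#' @param test_length_s Expected place-test length in seconds.
#' @return `study`, invisibly, if valid.
#' @export
validate_study <- function(study, test_length_s = 1200) {
  rt <- study$reflex_trials
  need <- c("animal", "day", "session", "paw", "trial_index", "latency_s")
  if (!all(need %in% names(rt)))
    stop("reflex_trials: missing column(s) ",
         paste(setdiff(need, names(rt)), collapse = ", "), call. = FALSE)
  bad <- which(rt$latency_s < 5 - 1e-9 | rt$latency_s > 20 + 1e-9)
  if (length(bad))
    stop("reflex_trials row ", bad[1], ": column latency_s value ",
         rt$latency_s[bad[1]], " outside [5, 20] s", call. = FALSE)
  cd <- study$conditioning
  if (any(cd$counts < 0))
    stop("conditioning row ", which(cd$counts < 0)[1],
         ": column counts is negative", call. = FALSE)
  pairs <- table(cd$animal, cd$day, cd$drug)
  if (length(pairs) && any(pairs != 1))
    stop("conditioning: each animal/day must have exactly one VEH and one ",
         "OXY record", call. = FALSE)
  pt <- study$place_tests
  if (any(pt$time_s < -1e-9))
    stop("place_tests row ", which(pt$time_s < -1e-9)[1],
         ": column time_s is negative", call. = FALSE)
  sums <- tapply(pt$time_s, interaction(pt$animal, pt$day, drop = TRUE), sum)
  off <- which(abs(sums - test_length_s) > 1e-6)
  if (length(off))
    stop("place_tests: compartment times for ", names(sums)[off[1]],
         " sum to ", format(sums[off[1]]), ", expected ", test_length_s,
         call. = FALSE)
  arms <- unique(study$animals$surgery_arm)
  if (!all(arms %in% c("CCI", "sham")))
    stop("animals: surgery_arm must be 'CCI' or 'sham'", call. = FALSE)
  invisible(study)
}

#' Write a study dataset as four tidy CSV files
#'
#' Writes `reflex_trials.csv`, `conditioning.csv`, `place_tests.csv` and
#' `animals.csv` into `dir`, plus a JSON echo of the generating
#' configuration (`config.json`) when the dataset carries one.
#'
#' @param study A `study_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$reflex_trials, file.path(dir, "reflex_trials.csv"),
                   row.names = FALSE)
  utils::write.csv(study$conditioning, file.path(dir, "conditioning.csv"),
                   row.names = FALSE)
  utils::write.csv(study$place_tests, file.path(dir, "place_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(study$animals, file.path(dir, "animals.csv"),
                   row.names = FALSE)
  if (!is.null(study$config)) {
    cfg <- unclass(study$config)
    cfg$latent_corr <- as.data.frame(cfg$latent_corr)
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a study dataset from tidy CSV files
#'
#' Inverse of [write_study()]; user-supplied data in the same four-file
#' schema is accepted.  The result is validated before being returned.
#'
#' @param dir Directory holding the four CSVs.
#' @param test_length_s Expected place-test length for validation.
#' @return A `study_dataset` (without config/traits unless present on disk).
#' @export
read_study <- function(dir, test_length_s = 1200) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  study <- structure(list(
    animals = rd("animals.csv"),
    reflex_trials = rd("reflex_trials.csv"),
    conditioning = rd("conditioning.csv"),
    place_tests = rd("place_tests.csv")
  ), class = "study_dataset")
  validate_study(study, test_length_s = test_length_s)
  study
}
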
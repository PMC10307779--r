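# Independent oracles and shared fixtures for the test suite.  Oracles are
# deliberately written by a different route than the implementation they
# check (normal equations vs centered sums, explicit SS decomposition vs
# lm/anova, per-pair cor.test loop vs vectorized cor).

# OLS slope/intercept via the normal equations, solved directly
oracle_slope <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# within-subjects one-way ANOVA by explicit sums of squares
oracle_rm_anova <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  grand <- mean(mat)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_treat <- n * sum((colMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_treat
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  Fv <- (ss_treat / df1) / (ss_err / df2)
  list(F = Fv, df = c(df1, df2), p = pf(Fv, df1, df2, lower.tail = FALSE))
}

# brute-force pairwise-complete correlation matrices via cor.test per pair
oracle_corr <- function(table, columns) {
  m <- length(columns)
  r <- p <- matrix(NA_real_, m, m, dimnames = list(columns, columns))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 1
      } else {
        xi <- table[[columns[i]]]
        yj <- table[[columns[j]]]
        ok <- !is.na(xi) & !is.na(yj)
        ct <- cor.test(xi[ok], yj[ok], method = "pearson")
        r[i, j] <- unname(ct$estimate)
        p[i, j] <- ct$p.value
      }
    }
  }
  list(r = r, p = p)
}

# Noise-free configuration in a clip-free regime: all sampling noise off and
# trait ranges kept well inside the latency window / positive-count region,
# so the measure pipeline inverts the generator exactly.
noise_free_config <- function(n_animals = 15L, seed = 101L, ...) {
  generator_config(
    n_animals = n_animals, seed = seed,
    trait_means = c(basal_latency = 15, latency_decline = 0.667,
                    basal_loco = 675, loco_habituation = 8.7,
                    oxy_loco_boost = 442, sensitization_slope = 104,
                    cpp_strength = 120, extinction_rate = 4.4),
    trait_sds = c(basal_latency = 0.8, latency_decline = 0.15,
                  basal_loco = 50, loco_habituation = 0.8,
                  oxy_loco_boost = 80, sensitization_slope = 40,
                  cpp_strength = 40, extinction_rate = 1.2),
    trial_noise_sd = 0, count_dispersion = 0, cpp_noise_sd = 0,
    ...
  )
}

# Linear-regime configuration: realistic sampling noise (trial noise, count
# overdispersion, place-test noise) but trait locations/scales chosen so the
# apparatus floors and ceilings (20 s latency cutoff, zero-count floor,
# 1200 s composition) essentially never censor an animal.  Used for the
# correlation-recovery property, which concerns the derivation machinery,
# not the censoring that paper-anchored trait SDs would induce.
linear_regime_config <- function(n_animals = 200L, seed = 1L, ...) {
  generator_config(
    n_animals = n_animals, seed = seed,
    trait_means = c(basal_latency = 15, latency_decline = 0.667,
                    basal_loco = 675, loco_habituation = 8.7,
                    oxy_loco_boost = 2000, sensitization_slope = 104,
                    cpp_strength = 120, extinction_rate = 4.4),
    trait_sds = c(basal_latency = 1.2, latency_decline = 0.75,
                  basal_loco = 218, loco_habituation = 2.6,
                  oxy_loco_boost = 594, sensitization_slope = 168,
                  cpp_strength = 80, extinction_rate = 2),
    trial_noise_sd = 0.5, count_dispersion = 5e-4, cpp_noise_sd = 15,
    pretest_oxy_s = 500, pretest_center_s = 300,
    ...
  )
}

# Measures implied by the planted traits in the clip-free noise-free regime;
# the habituation column depends on whether the square-root transform fired.
expected_pre_measures <- function(traits, hab_transformed) {
  data.frame(
    animal = traits$animal,
    `Basal reflex pain` = traits$basal_latency,
    `Rate of change in reflex pain` = traits$latency_decline,
    `Basal loco` = traits$basal_loco,
    `Rate of loco habituation` = if (hab_transformed) traits$loco_habituation
                                 else traits$loco_habituation^2,
    `Acute OXY loco` = traits$oxy_loco_boost,
    `Rate of behavioral sensitization` = traits$sensitization_slope,
    `CPP at first test` = traits$cpp_strength,
    `Rate of CPP extinction` = traits$extinction_rate,
    check.names = FALSE
  )
}

# Three-block latent correlation mirroring the reported cluster membership:
# {basal reflex pain, sensitization, extinction}, {rate of change in reflex
# pain, basal loco, habituation, acute drug loco}, {CPP strength} alone.
block_latent_corr <- function(within = 0.75) {
  tr <- trait_names()
  R <- diag(8)
  dimnames(R) <- list(tr, tr)
  b1 <- c("basal_latency", "sensitization_slope", "extinction_rate")
  b2 <- c("latency_decline", "basal_loco", "loco_habituation",
          "oxy_loco_boost")
  for (b in list(b1, b2))
    for (i in b) for (j in b) if (i != j) R[i, j] <- within
  # honor the reported signs: latency measures anti-correlate with their
  # block partners; |r| (hence the distance) is unchanged
  sgn <- c(basal_latency = -1, latency_decline = -1, basal_loco = 1,
           loco_habituation = 1, oxy_loco_boost = 1,
           sensitization_slope = 1, cpp_strength = 1, extinction_rate = 1)
  R * outer(sgn, sgn)
}

# block ids of the eight pre-surgery measures under block_latent_corr(),
# in pre_measure_names() order
block_membership <- c(1, 2, 2, 2, 2, 1, 3, 1)

same_partition <- function(a, b) {
  a <- unname(a)
  b <- unname(b)
  length(a) == length(b) && all(outer(a, a, "==") == outer(b, b, "=="))
}

# n x m MVN measure table with planted block-correlation structure;
# `between` optionally sets heterogeneous between-block correlations (a
# blocks x blocks matrix).  Heterogeneity matters for MDS-based recovery:
# equal between-block correlations put the block centroids on a regular
# simplex, whose 2-D projection is degenerate for four or more blocks.
planted_block_table <- function(n, block_sizes, within = 0.8, seed = 1,
                                between = NULL, prefix = "m") {
  m <- sum(block_sizes)
  R <- matrix(0, m, m)
  stop_at <- cumsum(block_sizes)
  start_at <- c(1, head(stop_at, -1) + 1)
  for (a in seq_along(block_sizes)) {
    for (b in seq_along(block_sizes)) {
      R[start_at[a]:stop_at[a], start_at[b]:stop_at[b]] <-
        if (a == b) within else if (is.null(between)) 0 else between[a, b]
    }
  }
  diag(R) <- 1
  stopifnot(min(eigen(R, TRUE, only.values = TRUE)$values) > -1e-8)
  ed <- eigen(R, symmetric = TRUE)
  L <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0))) %*% t(ed$vectors)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m) %*% t(L)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  colnames(X) <- paste0(prefix, seq_len(m))
  as.data.frame(X)
}
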
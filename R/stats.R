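#' @title Group-level inferential tests
#' @description Pure wrappers returning a uniform result structure: the
#'   statistic name and value, degrees of freedom where applicable and the
#'   two-tailed p value.  All p values are two-tailed and uncorrected.
#' @param statistic,df,p,name internal constructor fields
#' @name stats_battery
#' @keywords internal
NULL

etho_test <- function(name, statistic, df = NULL, p, extra = list()) {
  structure(c(list(statistic_name = name,
                   statistic = unname(statistic),
                   df = if (is.null(df)) NULL else unname(df),
                   p = unname(p)), extra),
            class = "etho_test")
}

#' @export
print.etho_test <- function(x, ...) {
  dfs <- if (is.null(x$df)) "" else
    paste0("(", paste(format(x$df, digits = 4), collapse = ", "), ")")
  cat(sprintf("%s%s = %.4f, p = %.4g\n", x$statistic_name, dfs,
              x$statistic, x$p))
  invisible(x)
}

#' One-sample t test
#'
#' Tests the sample mean against a hypothesized value `mu0`.
#'
#' @param values Numeric sample (n >= 2, non-constant).
#' @param mu0 Hypothesized mean.
#' @return An `etho_test` with statistic `t`, `df = n - 1` and two-tailed p.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  if (length(values) < 2L)
    stop("one_sample_t: need n >= 2", call. = FALSE)
  if (stats::sd(values) == 0) {
    if (mean(values) == mu0)
      return(etho_test("t", 0, length(values) - 1L, 1))
    stop("one_sample_t: zero sample variance", call. = FALSE)
  }
  tt <- stats::t.test(values, mu = mu0)
  etho_test("t", tt$statistic, tt$parameter, tt$p.value)
}

#' Paired t test
#'
#' One-sample t test on the paired differences against zero.
#'
#' @param x,y Equal-length numeric vectors.
#' @return An `etho_test` (statistic `t`, df `n - 1`).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    stop("paired_t: unequal lengths", call. = FALSE)
  one_sample_t(x - y, 0)
}

#' Unpaired (pooled-variance Student) t test
#'
#' Classical two-sample t with pooled variance, `df = n1 + n2 - 2` (the
#' integer df convention used throughout the reported comparisons; not
#' Welch).
#'
#' @param x,y Numeric group samples (each n >= 2).
#' @return An `etho_test` (statistic `t`).
#' @export
unpaired_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("unpaired_t: both groups need n >= 2", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(etho_test("t", 0, length(x) + length(y) - 2L, 1))
    stop("unpaired_t: zero pooled variance", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  etho_test("t", tt$statistic, tt$parameter, tt$p.value)
}

#' One-way repeated-measures (within-subjects) ANOVA
#'
#' Total sum of squares is partitioned into subjects, treatment (sessions)
#' and error; `F = MS_treatment / MS_error` on `(k - 1), (k - 1)(n - 1)`
#' degrees of freedom.  No sphericity correction is applied, so the printed
#' df are integers.
#'
#' @param mat Complete numeric matrix, animals in rows, sessions in columns.
#' @return An `etho_test` with statistic `F` and `df = c(k - 1, (k-1)(n-1))`.
#' @export
rm_anova_one_way <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("rm_anova_one_way: incomplete matrix", call. = FALSE)
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2L || k < 2L)
    stop("rm_anova_one_way: need >= 2 animals and >= 2 sessions",
         call. = FALSE)
  long <- data.frame(
    y = as.vector(mat),
    animal = factor(rep(seq_len(n), times = k)),
    session = factor(rep(seq_len(k), each = n))
  )
  tab <- withCallingHandlers(
    stats::anova(stats::lm(y ~ animal + session, data = long)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  df1 <- tab["session", "Df"]
  df2 <- tab["Residuals", "Df"]
  ss_sess <- tab["session", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  # degenerate designs: treat sums of squares at rounding level as zero
  eps <- 1e-12 * (sum(long$y^2) + 1)
  if (ss_sess <= eps) {
    Fv <- 0
    p <- 1
  } else if (ss_err <= eps) {
    Fv <- Inf
    p <- 0
  } else {
    Fv <- (ss_sess / df1) / (ss_err / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  etho_test("F", Fv, c(df1, df2), p)
}

#' Shapiro-Wilk normality test
#'
#' Standard small-sample W statistic and p value (Royston approximation).
#'
#' @param values Numeric sample, 3 <= n <= 5000, non-constant.
#' @return An `etho_test` with statistic `W` (no df).
#' @export
shapiro_wilk <- function(values) {
  if (length(values) < 3L || length(values) > 5000L)
    stop("shapiro_wilk: n must be in [3, 5000]", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("shapiro_wilk: constant sample", call. = FALSE)
  sw <- stats::shapiro.test(values)
  etho_test("W", sw$statistic, NULL, sw$p.value)
}

#' Pearson correlation with t-based p value
#'
#' @param x,y Equal-length numeric vectors, n >= 3, non-constant.
#' @return An `etho_test` with statistic `r`, `df = n - 2`, and field `r`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("pearson: unequal lengths", call. = FALSE)
  if (length(x) < 3L) stop("pearson: need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson: constant input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  etho_test("r", ct$estimate, ct$parameter, ct$p.value,
            extra = list(r = unname(ct$estimate)))
}

#' Two-tailed p value for a Pearson r at sample size n
#'
#' Uses the exact t transform `t = r sqrt(n - 2) / sqrt(1 - r^2)` on
#' `n - 2` degrees of freedom.  `|r| = 1` returns the boundary p = 0.
#'
#' @param r Correlation coefficient, |r| <= 1.
#' @param n Sample size (>= 3).
#' @return Two-tailed probability in \[0, 1\].
#' @export
p_from_r <- function(r, n) {
  if (n < 3) stop("p_from_r: need n >= 3", call. = FALSE)
  if (abs(r) > 1 + 1e-12) stop("p_from_r: |r| must be <= 1", call. = FALSE)
  r <- pmin(pmax(r, -1), 1)
  if (abs(r) == 1) return(0)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Mann-Whitney U test (normal approximation)
#'
#' U from rank sums with midrank ties; Z via the normal approximation with
#' tie-corrected variance and no continuity correction;
#' `p = 2 (1 - Phi(|Z|))`.
#'
#' @param x,y Numeric group samples.
#' @return An `etho_test` with statistic `Z` and fields `U` and `U_prime`.
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L)
    stop("mann_whitney: both groups must be non-empty", call. = FALSE)
  all_v <- c(x, y)
  rk <- rank(all_v)  # midranks
  R1 <- sum(rk[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  N <- n1 + n2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  varU <- n1 * n2 / 12 * ((N + 1) - tie_term)
  Z <- if (varU == 0) 0 else (U1 - n1 * n2 / 2) / sqrt(varU)
  p <- 2 * stats::pnorm(-abs(Z))
  etho_test("Z", Z, NULL, min(p, 1),
            extra = list(U = unname(U1), U_prime = unname(U2)))
}
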
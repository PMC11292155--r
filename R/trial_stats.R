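#' A printed group summary (n, mean, sample SD)
#'
#' @param n group size (>= 2).
#' @param mean group mean.
#' @param sd sample standard deviation (n - 1 denominator, >= 0).
#' @return an object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  if (!is.numeric(n) || n < 2) stop("n must be >= 2", call. = FALSE)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

new_test_result <- function(statistic, df, p, method, effect_size = NULL) {
  structure(list(statistic = statistic, df = df, p_two_sided = p,
                 method = method, effect_size = effect_size),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %.4g, two-sided p = %.4g%s\n",
              x$method, x$statistic, x$df, x$p_two_sided,
              if (!is.null(x$effect_size))
                sprintf(", effect size = %.3f", x$effect_size) else ""))
  invisible(x)
}

#' Two-sample t test from printed group summaries
#'
#' Pooled form: `t = (mean_a - mean_b) / (s_p * sqrt(1/n_a + 1/n_b))` with
#' `s_p^2 = ((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)` and
#' `df = n_a + n_b - 2`; Welch form uses the separate-variance statistic and
#' Satterthwaite df.  Two-sided p from the t distribution.
#'
#' @param a,b [group_summary()] objects (a is conventionally the control
#'   group, so the statistic is control minus intervention).
#' @param pooled use the pooled-variance (Student) form; `FALSE` for Welch.
#' @return a `test_result`.
#' @export
t_from_summary <- function(a, b, pooled = TRUE) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  dm <- a$mean - b$mean
  if (pooled) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2) * sqrt(1 / a$n + 1 / b$n)
    method <- "Two-sample t test (pooled variance)"
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    method <- "Welch two-sample t test"
  }
  if (se == 0) stop("zero standard error: degenerate summaries", call. = FALSE)
  t <- dm / se
  new_test_result(t, df, 2 * stats::pt(-abs(t), df), method)
}

#' Two-sample t test from raw samples
#'
#' Thin wrapper over [stats::t.test()]; identical (to floating tolerance) to
#' [t_from_summary()] applied to the samples' own n/mean/sd.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param pooled pooled-variance (Student) form; `FALSE` for Welch.
#' @return a `test_result`.
#' @export
t_from_raw <- function(x, y, pooled = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs >= 2 values", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = pooled)
  new_test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  if (pooled) "Two-sample t test (pooled variance)"
                  else "Welch two-sample t test")
}

#' Cohen's d from group summaries
#'
#' Absolute standardised mean difference with the pooled sample SD:
#' `d = |mean_a - mean_b| / s_p`.
#'
#' @param a,b [group_summary()] objects.
#' @return Cohen's d (non-negative).
#' @export
cohens_d_from_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 == 0) stop("zero pooled SD", call. = FALSE)
  abs(a$mean - b$mean) / sqrt(sp2)
}

#' Mann-Whitney U test
#'
#' `U` counts pairs with `x_i > y_j` (ties count one half).  For combined
#' sample sizes up to `exact_max` the two-sided p value is computed by exact
#' enumeration over all `choose(n+m, n)` group labelings of the pooled
#' values (so ties are handled exactly); otherwise the normal approximation
#' with the usual tie-corrected variance is used, without continuity
#' correction.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_max largest combined size for exact enumeration.
#' @return a `test_result` with the U statistic.
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("non-empty samples required", call. = FALSE)
  U_of <- function(xs, ys) {
    sum(vapply(xs, function(xi) sum(xi > ys) + 0.5 * sum(xi == ys),
               numeric(1)))
  }
  U <- U_of(x, y)
  mu <- n * m / 2
  if (n + m <= exact_max) {
    pool <- c(x, y)
    splits <- utils::combn(n + m, n)
    dev_obs <- abs(U - mu) - 1e-9
    devs <- apply(splits, 2, function(idx)
      abs(U_of(pool[idx], pool[-idx]) - mu))
    p <- mean(devs >= dev_obs)
    method <- "Mann-Whitney U test (exact enumeration)"
  } else {
    N <- n + m
    ties <- table(c(x, y))
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {  # all values tied
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  new_test_result(U, NA_real_, min(p, 1), method)
}

#' Sample size for comparing two means
#'
#' Smallest per-group n giving at least the target power for a two-sided
#' two-sample t test, found by iterating the noncentral-t power function
#' (via [stats::power.t.test()]); the closed-form normal-approximation value
#' `ceiling(2 (z_{1-alpha/2} + z_{power})^2 sd^2 / delta^2)` is reported
#' alongside.
#'
#' @param alpha two-sided significance level, in (0, 1).
#' @param power target power, in (0, 1).
#' @param mean_a,mean_b anticipated group means (must differ).
#' @param sd common standard deviation (> 0).
#' @return list with `n_per_group` (noncentral-t) and `n_normal_approx`.
#' @export
sample_size_two_means <- function(alpha, power, mean_a, mean_b, sd) {
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  delta <- abs(mean_a - mean_b)
  if (delta == 0) stop("means must differ", call. = FALSE)
  n_normal <- ceiling(2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 *
                        sd^2 / delta^2)
  n <- ceiling(stats::power.t.test(delta = delta, sd = sd, sig.level = alpha,
                                   power = power, type = "two.sample")$n)
  # confirm minimality: step down while power still meets the target
  while (n > 2 && stats::power.t.test(n = n - 1, delta = delta, sd = sd,
                                      sig.level = alpha,
                                      type = "two.sample")$power >= power)
    n <- n - 1
  list(n_per_group = as.integer(n), n_normal_approx = as.integer(n_normal))
}

#' Default Flow Short Scale item mapping
#'
#' The 13 items partition into 6 fluency-of-performance items, 4
#' absorption-by-activity items (fluency and absorption together are items
#' 1--10, whose mean is overall flow), and 3 perceived-importance items.
#' The instrument's item order is licensed content, so items are referenced
#' by index only; the 6/4 split within items 1--10 is corroborated by the
#' weighted-mean identity `flow = (6 fluency + 4 absorption) / 10`.
#'
#' @param fluency,absorption,importance integer index sets.
#' @return a named list of index sets, validated as a partition.
#' @export
fss_mapping <- function(fluency = 1:6, absorption = 7:10, importance = 11:13) {
  m <- list(fluency = as.integer(fluency), absorption = as.integer(absorption),
            importance = as.integer(importance))
  all_idx <- sort(unname(unlist(m)))
  if (!identical(all_idx, 1:13))
    stop("mapping must partition items 1..13", call. = FALSE)
  if (length(m$fluency) != 6L || length(m$absorption) != 4L ||
      length(m$importance) != 3L)
    stop("mapping must split items 6 + 4 + 3", call. = FALSE)
  if (!setequal(c(m$fluency, m$absorption), 1:10))
    stop("fluency and absorption together must be items 1..10", call. = FALSE)
  m
}

#' Score one Flow Short Scale response
#'
#' Subscale scores are item means; overall flow is the mean of items 1--10
#' (the fluency and absorption items).
#'
#' @param items integer vector of 13 responses, each in 1..7.
#' @param mapping an [fss_mapping()].
#' @return an object of class `fss_scores` with `fluency`, `absorption`,
#'   `importance`, `flow`.
#' @export
score_fss <- function(items, mapping = fss_mapping()) {
  if (length(items) != 13L)
    stop("an FSS response has exactly 13 items", call. = FALSE)
  if (any(is.na(items)) || any(items != round(items)) ||
      any(items < 1) || any(items > 7))
    stop("FSS items must be integers in 1..7", call. = FALSE)
  structure(list(fluency = mean(items[mapping$fluency]),
                 absorption = mean(items[mapping$absorption]),
                 importance = mean(items[mapping$importance]),
                 flow = mean(items[sort(c(mapping$fluency,
                                          mapping$absorption))])),
            class = "fss_scores")
}

#' Simulate Flow Short Scale responses from a latent-flow model
#'
#' Each respondent draws a latent flow level from
#' `N(latent_mean, latent_sd)`; each item adds independent `N(0, item_sd)`
#' noise, is rounded, and clamped to the 1..7 scale.  A synthetic fixture
#' generator for exercising the raw-data analysis path; it does not model
#' real psychometric item behaviour.
#'
#' @param n respondents.
#' @param latent_mean,latent_sd latent flow distribution.
#' @param item_sd per-item noise SD.
#' @return an `n x 13` integer matrix of responses.
#' @export
simulate_fss_responses <- function(n, latent_mean, latent_sd = 0.8,
                                   item_sd = 1.0) {
  latent <- stats::rnorm(n, latent_mean, latent_sd)
  items <- round(matrix(latent, n, 13) + matrix(stats::rnorm(n * 13, 0, item_sd), n, 13))
  items[items < 1] <- 1L
  items[items > 7] <- 7L
  storage.mode(items) <- "integer"
  colnames(items) <- paste0("item", 1:13)
  items
}

#' Analysis-plan group comparison for one variable
#'
#' Implements the trial's plan: Shapiro-Wilk normality screen at
#' `alpha_normality` on both groups; if both pass, an independent-samples t
#' test (pooled unless an F test rejects equality of variances, in which
#' case Welch); otherwise a Mann-Whitney U test.
#'
#' @param x,y raw samples (x conventionally the control group).
#' @param alpha_normality screening level for Shapiro-Wilk and the variance
#'   F test.
#' @return a `test_result`; for t tests, `effect_size` carries Cohen's d.
#' @export
compare_groups <- function(x, y, alpha_normality = 0.05) {
  normal <- function(v) {
    if (length(unique(v)) < 3) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha_normality
  }
  if (normal(x) && normal(y)) {
    pooled <- stats::var.test(x, y)$p.value >= alpha_normality
    res <- t_from_raw(x, y, pooled = pooled)
    res$effect_size <- cohens_d_from_summary(
      group_summary(length(x), mean(x), stats::sd(x)),
      group_summary(length(y), mean(y), stats::sd(y)))
    res
  } else {
    mann_whitney(x, y)
  }
}

#' The trial's printed outcome summaries
#'
#' Per-arm n/mean/SD for the seven compared variables: the four Flow Short
#' Scale scores and the three gameplay outcomes, for the unfacilitated
#' control arm (n = 26) and the facilitated intervention arm (n = 22).
#'
#' @return a data.frame with one row per variable.
#' @export
trial_summaries <- function() {
  data.frame(
    variable = c("overall_flow", "fluency", "absorption", "importance",
                 "hours_ideal_glucose", "metformin_errors", "evacuations"),
    is_fss = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    n_control = 26L, mean_control = c(4.4, 4.03, 4.96, 4.26, 2.66, 2.77, 1.58),
    sd_control = c(0.89, 1.16, 0.83, 1.39, 1.36, 1.88, 1.94),
    n_intervention = 22L,
    mean_intervention = c(4.95, 4.52, 5.6, 4.35, 2.35, 2.73, 0.64),
    sd_intervention = c(0.85, 1.06, 0.87, 1.78, 1.09, 1.67, 0.95))
}

#' Recompute the trial's t tests and effect sizes from printed summaries
#'
#' Runs the pooled two-sample t test (control minus intervention, df = 46
#' for the default summaries) on every row and Cohen's d on the Flow Short
#' Scale rows.  `abs_t` is reported alongside the signed statistic.
#'
#' @param summaries a data.frame as returned by [trial_summaries()].
#' @return a data.frame with columns `variable`, `t`, `abs_t`, `df`,
#'   `p_two_sided`, `cohens_d` (NA for non-FSS rows).
#' @export
reproduce_trial_table <- function(summaries = trial_summaries()) {
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    r <- summaries[i, ]
    a <- group_summary(r$n_control, r$mean_control, r$sd_control)
    b <- group_summary(r$n_intervention, r$mean_intervention,
                       r$sd_intervention)
    tt <- t_from_summary(a, b, pooled = TRUE)
    data.frame(variable = r$variable, t = tt$statistic,
               abs_t = abs(tt$statistic), df = tt$df,
               p_two_sided = tt$p_two_sided,
               cohens_d = if (r$is_fss) cohens_d_from_summary(a, b)
                          else NA_real_)
  })
  do.call(rbind, rows)
}
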
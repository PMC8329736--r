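#' Paired comparison of vowel space areas between registers
#'
#' Classical two-tailed paired-samples t-test, used to establish whether the
#' IDS vowel space is larger than the ADS vowel space across speakers.
#'
#' @param a,b Numeric vectors of per-speaker areas, paired by position
#'   (e.g. IDS and ADS).
#' @return A `paired_test_result`: `t`, `df` (= n - 1), two-tailed `p`,
#'   per-arm means and SDs, and `n`.
#' @examples
#' paired_t_test(c(1, 2, 3), c(0, 0, 0))$t  # 3.464
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must be paired (equal length)")
  n <- length(a)
  if (n < 2) stop("paired t-test needs at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("zero variance of paired differences; t statistic undefined")
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  out <- list(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value,
    mean_a = mean(a), mean_b = mean(b),
    sd_a = stats::sd(a), sd_b = stats::sd(b),
    mean_difference = mean(d), sd_difference = stats::sd(d),
    n = n
  )
  class(out) <- "paired_test_result"
  out
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<paired_test_result> t(%d) = %.2f, p = %.3f\n", x$df, x$t, x$p))
  cat(sprintf("  mean a = %.1f (SD %.1f), mean b = %.1f (SD %.1f), n = %d\n",
              x$mean_a, x$sd_a, x$mean_b, x$sd_b, x$n))
  invisible(x)
}

#' Outlier exclusion policy
#'
#' @param type `"none"`, `"absolute"` (exclude subjects whose mean score
#'   exceeds `cutoff`), or `"z"` (exclude subjects whose mean score lies
#'   more than `k` leave-one-out standard deviations from the leave-one-out
#'   mean of the remaining subjects).
#' @param cutoff Absolute cutoff in points (policy `"absolute"`).
#' @param k Standard-deviation multiplier (policy `"z"`, default 3).
#' @return An `outlier_policy` object.
#' @export
outlier_policy <- function(type = c("z", "absolute", "none"), cutoff = NULL, k = 3) {
  type <- match.arg(type)
  if (type == "absolute" && (is.null(cutoff) || !is.numeric(cutoff))) {
    stop("policy 'absolute' requires a numeric `cutoff`")
  }
  if (type == "z" && (!is.numeric(k) || k <= 0)) stop("`k` must be positive")
  structure(list(type = type, cutoff = cutoff, k = k), class = "outlier_policy")
}

#' Exclude outlying subject summaries
#'
#' Deterministic partition of per-subject WCM-SE summaries under an
#' explicit [outlier_policy()], with logged reasons. The default z policy
#' computes each subject's z score against the leave-one-out mean and SD of
#' the other subjects, so an extreme subject cannot mask itself.
#'
#' @param summaries A tibble with columns `subject_id` and `mean_score`
#'   (e.g. from [subject_wcm_table()]), or a list of `subject_wcm_summary`
#'   objects.
#' @param policy An [outlier_policy()].
#' @return List with `kept` and `excluded` tibbles and a `log` of reasons.
#' @export
exclude_outliers <- function(summaries, policy = outlier_policy("z", k = 3)) {
  if (!inherits(policy, "outlier_policy")) stop("unknown outlier policy")
  if (is.list(summaries) && !is.data.frame(summaries) &&
      all(vapply(summaries, inherits, logical(1), "subject_wcm_summary"))) {
    summaries <- dplyr::bind_rows(lapply(summaries, function(s) {
      tibble::tibble(subject_id = s$subject_id,
                     n_vocalizations = s$n_vocalizations,
                     mean_score = s$mean_score)
    }))
  }
  stopifnot(all(c("subject_id", "mean_score") %in% names(summaries)))
  x <- summaries$mean_score
  n <- length(x)
  out <- logical(n)
  reason <- character(n)
  if (policy$type == "absolute") {
    out <- x > policy$cutoff
    reason[out] <- sprintf("mean score %.2f exceeds cutoff %g", x[out],
                           policy$cutoff)
  } else if (policy$type == "z") {
    if (n >= 3) {
      for (i in seq_len(n)) {
        rest <- x[-i]
        s <- stats::sd(rest)
        if (s == 0) next
        z <- (x[i] - mean(rest)) / s
        if (abs(z) > policy$k) {
          out[i] <- TRUE
          reason[i] <- sprintf(
            "mean score %.2f is %.1f leave-one-out SDs from the others", x[i], z)
        }
      }
    }
  }
  log <- tibble::tibble(subject_id = summaries$subject_id[out],
                        mean_score = x[out], reason = reason[out])
  list(kept = summaries[!out, , drop = FALSE],
       excluded = summaries[out, , drop = FALSE],
       log = log,
       policy = policy)
}

#' Regression of infant complexity on parental articulation change
#'
#' Ordinary least squares fit of per-subject mean WCM-SE score on the
#' speaker's VSA difference, with intercept; the slope is tested with the
#' model F-test (equivalently the two-sided t-test on the slope).
#'
#' @param x VSA differences (one per dyad), non-constant.
#' @param y Mean WCM-SE scores, same length, n >= 3.
#' @return A `regression_result`: `beta` (points per area unit),
#'   `intercept`, `F`, `df` (= c(1, n - 2)), `r_squared`, `p`, `n`, and the
#'   underlying `lm` fit.
#' @export
fit_regression <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) stop("regression needs at least 3 dyads")
  if (stats::sd(x) == 0) stop("constant predictor: VSA differences do not vary")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  out <- list(
    beta = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    F = unname(sm$fstatistic[1]),
    df = c(1L, n - 2L),
    r_squared = sm$r.squared,
    p = unname(stats::pf(sm$fstatistic[1], 1, n - 2, lower.tail = FALSE)),
    n = n,
    fit = fit
  )
  class(out) <- "regression_result"
  out
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> F(%d,%d) = %.2f, beta = %.3g, R^2 = %.3f, p = %.3f, n = %d\n",
    x$df[1], x$df[2], x$F, x$beta, x$r_squared, x$p, x$n))
  invisible(x)
}

#' Predicted complexity increase for a given articulation change
#'
#' Effect-size report for the fitted slope: the model-predicted change in
#' mean WCM-SE score for a `delta` change in VSA difference (e.g. 10,000
#' Hz^2), at full precision and display-rounded to two decimals.
#'
#' @param beta Slope in points per area unit.
#' @param delta Change in area units.
#' @return List with `value` (full precision) and `display` (2 decimals).
#' @examples
#' predicted_increase(8.07e-6, 10000)$display  # "0.08"
#' @export
predicted_increase <- function(beta, delta) {
  value <- beta * delta
  list(value = value, display = sprintf("%.2f", value))
}
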
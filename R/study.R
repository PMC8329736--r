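#' Study configuration
#'
#' Bundles the analysis constants: the f0 exclusion threshold, the central
#' window fraction for formant averaging, the frequency scale(s), the
#' outlier policy applied to subject mean scores, and the effect-size delta
#' for the predicted-increase report. Defaults are the values used in the
#' headline analysis: 350 Hz, mid 40%, Hz scale with a Bark re-expression,
#' leave-one-out z exclusion at 3 SD, 10,000 Hz^2.
#'
#' @param f0_max f0 exclusion threshold in Hz.
#' @param window_fraction Central fraction of the vowel used for formant
#'   averaging, in (0, 1].
#' @param scales Character vector, subset of `c("hz", "bark")`; the first
#'   element is the primary scale.
#' @param outlier An [outlier_policy()].
#' @param predicted_delta Area change (primary-scale units^2) for the
#'   effect-size report.
#' @return A `study_config` object.
#' @export
study_config <- function(f0_max = 350, window_fraction = 0.4,
                         scales = c("hz", "bark"),
                         outlier = outlier_policy("z", k = 3),
                         predicted_delta = 10000) {
  if (!is.numeric(f0_max) || f0_max <= 0) stop("`f0_max` must be positive")
  if (!is.numeric(window_fraction) || window_fraction <= 0 || window_fraction > 1) {
    stop("`window_fraction` must be in (0, 1]")
  }
  scales <- match.arg(scales, c("hz", "bark"), several.ok = TRUE)
  if (!inherits(outlier, "outlier_policy")) stop("`outlier` must be an outlier_policy")
  if (!is.numeric(predicted_delta)) stop("`predicted_delta` must be numeric")
  structure(list(f0_max = f0_max, window_fraction = window_fraction,
                 scales = scales, outlier = outlier,
                 predicted_delta = predicted_delta),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Recognized keys: `version`, `f0_max`, `window_fraction`, `scales`,
#' `outlier` (a mapping with `type` and optionally `cutoff`/`k`), and
#' `predicted_delta`. Unknown keys are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("version", "f0_max", "window_fraction", "scales", "outlier",
               "predicted_delta")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  pol <- if (is.null(raw$outlier)) {
    outlier_policy("z", k = 3)
  } else {
    bad <- setdiff(names(raw$outlier), c("type", "cutoff", "k"))
    if (length(bad) > 0) stop("unknown outlier key(s): ", paste(bad, collapse = ", "))
    outlier_policy(raw$outlier$type %||% "z", cutoff = raw$outlier$cutoff,
                   k = raw$outlier$k %||% 3)
  }
  study_config(
    f0_max = raw$f0_max %||% 350,
    window_fraction = raw$window_fraction %||% 0.4,
    scales = raw$scales %||% c("hz", "bark"),
    outlier = pol,
    predicted_delta = raw$predicted_delta %||% 10000
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full two-arm study
#'
#' Vowel-space arm: f0 screening, mid-window formant extraction, per-speaker
#' point-vowel means and areas per register, IDS - ADS differences, and a
#' paired t-test of the areas — on the primary scale and, when configured,
#' re-expressed in Bark. Complexity arm: transcription parsing (row-level
#' errors are collected, not fatal), WCM-SE scoring, subject means, outlier
#' exclusion, and the regression of mean score on VSA difference. The same
#' subject exclusion is applied to every scale's regression. Dyads are
#' joined on `speaker_id` = `subject_id`.
#'
#' @param tokens Vowel-token tibble (see [vowel_tokens()] or
#'   [read_token_table()]).
#' @param transcriptions Tibble with `subject_id` and `transcription`
#'   columns (see [read_transcriptions()]).
#' @param config A [study_config()].
#' @return A `study_result`: per-scale `vsa` tables and `paired` tests,
#'   per-scale `regression` results, the `excluded` subject log, the
#'   `predicted` effect-size report on the primary scale, and an `audit`
#'   of per-stage counts.
#' @export
run_study <- function(tokens, transcriptions, config = study_config()) {
  stopifnot(inherits(config, "study_config"))

  vsa_arm <- list()
  paired <- list()
  for (sc in config$scales) {
    vsa_arm[[sc]] <- with_stage(paste0("vsa-", sc), speaker_vsa_table(
      tokens, scale = sc, f0_max = config$f0_max,
      fraction = config$window_fraction))
    paired[[sc]] <- with_stage(paste0("paired-t-", sc), paired_t_test(
      vsa_arm[[sc]]$table$vsa_ids, vsa_arm[[sc]]$table$vsa_ads))
  }

  # parse with per-row error collection
  stopifnot(all(c("subject_id", "transcription") %in% names(transcriptions)))
  uniq <- unique(transcriptions$transcription)
  parse_err <- vapply(uniq, function(s) {
    tryCatch({ parse_transcription(s); NA_character_ },
             error = function(e) conditionMessage(e))
  }, character(1))
  bad_strings <- uniq[!is.na(parse_err)]
  bad_rows <- transcriptions$transcription %in% bad_strings
  parse_log <- tibble::tibble(
    subject_id = transcriptions$subject_id[bad_rows],
    transcription = transcriptions$transcription[bad_rows],
    error = parse_err[match(transcriptions$transcription[bad_rows], uniq)]
  )
  usable <- transcriptions[!bad_rows, , drop = FALSE]
  if (nrow(usable) == 0) stop("stage wcm-parse: no parsable transcriptions")

  summaries <- with_stage("wcm-score", subject_wcm_table(usable))
  screened <- with_stage("wcm-outliers", exclude_outliers(summaries, config$outlier))

  primary <- config$scales[1]
  regression <- list()
  for (sc in config$scales) {
    joined <- dplyr::inner_join(
      screened$kept,
      vsa_arm[[sc]]$table,
      by = c(subject_id = "speaker_id"))
    regression[[sc]] <- with_stage(paste0("regression-", sc), fit_regression(
      joined$difference, joined$mean_score))
  }
  predicted <- predicted_increase(regression[[primary]]$beta, config$predicted_delta)

  audit <- list(
    n_tokens = nrow(tokens),
    n_tokens_kept = nrow(tokens) - nrow(vsa_arm[[primary]]$exclusions),
    n_tokens_excluded_f0 = nrow(vsa_arm[[primary]]$exclusions),
    n_speakers = nrow(vsa_arm[[primary]]$table),
    n_vocalizations = nrow(transcriptions),
    n_vocalizations_failed = sum(bad_rows),
    n_subjects = nrow(summaries),
    n_subjects_excluded = nrow(screened$excluded)
  )

  out <- list(
    config = config,
    vsa = vsa_arm,
    paired = paired,
    regression = regression,
    predicted = predicted,
    subject_scores = summaries,
    excluded_subjects = screened$log,
    parse_errors = parse_log,
    audit = audit
  )
  class(out) <- "study_result"
  out
}

#' @export
print.study_result <- function(x, ...) {
  primary <- x$config$scales[1]
  pt <- x$paired[[primary]]
  rg <- x$regression[[primary]]
  cat("<study_result>\n")
  cat(sprintf("  speakers: %d; tokens %d (excluded %d by f0 > %g Hz)\n",
              x$audit$n_speakers, x$audit$n_tokens, x$audit$n_tokens_excluded_f0,
              x$config$f0_max))
  cat(sprintf("  VSA (%s): IDS mean %.1f, ADS mean %.1f; t(%d) = %.2f, p = %.3f\n",
              primary, pt$mean_a, pt$mean_b, pt$df, pt$t, pt$p))
  cat(sprintf("  WCM-SE: %d subjects (%d excluded as outliers)\n",
              x$audit$n_subjects, x$audit$n_subjects_excluded))
  cat(sprintf("  regression (%s): F(%d,%d) = %.2f, beta = %.3g, R^2 = %.3f, p = %.3f\n",
              primary, rg$df[1], rg$df[2], rg$F, rg$beta, rg$r_squared, rg$p))
  cat(sprintf("  predicted increase per %g units^2: %s points\n",
              x$config$predicted_delta, x$predicted$display))
  invisible(x)
}
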
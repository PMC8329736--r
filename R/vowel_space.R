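#' Construct a formant track
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param f1,f2 First and second formant in Hz per sample, all positive.
#' @param f0 Optional fundamental-frequency track in Hz.
#' @return A `formant_track` tibble with columns `time`, `f1`, `f2` (and
#'   `f0` when supplied).
#' @export
formant_track <- function(times, f1, f2, f0 = NULL) {
  if (length(times) < 1) stop("a formant track needs at least one sample")
  if (length(f1) != length(times) || length(f2) != length(times)) {
    stop("`times`, `f1` and `f2` must have equal length")
  }
  if (!is.null(f0) && length(f0) != length(times)) {
    stop("`f0` must match the track length")
  }
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(f1 <= 0) || any(f2 <= 0) || (!is.null(f0) && any(f0 <= 0))) {
    stop("all frequencies must be positive")
  }
  out <- tibble::tibble(time = as.numeric(times), f1 = as.numeric(f1),
                        f2 = as.numeric(f2))
  if (!is.null(f0)) out$f0 <- as.numeric(f0)
  class(out) <- c("formant_track", class(out))
  out
}

point_vowels <- c("i", "ɑ", "u")

# "a" is accepted as an alias for the open back vowel label
normalize_vowel <- function(vowel) {
  v <- ifelse(vowel == "a", "ɑ", vowel)
  bad <- setdiff(unique(v), point_vowels)
  if (length(bad) > 0) {
    stop("not a point vowel: ", paste(bad, collapse = ", "))
  }
  v
}

#' Build a vowel token table
#'
#' One row per vowel production: speaker, register (IDS or ADS), point-vowel
#' category, median f0, and either a formant track (list-column `track`) or
#' pre-averaged point estimates `f1`, `f2`.
#'
#' @param speaker_id,register,vowel,median_f0 Vectors of equal length.
#' @param f1,f2 Optional pre-averaged formant values in Hz.
#' @param track Optional list of [formant_track()] objects.
#' @param token_id Optional identifiers; generated when missing.
#' @return A `vowel_token` tibble.
#' @export
vowel_tokens <- function(speaker_id, register, vowel, median_f0,
                         f1 = NULL, f2 = NULL, track = NULL, token_id = NULL) {
  n <- length(speaker_id)
  register <- as.character(register)
  if (!all(register %in% c("IDS", "ADS"))) {
    stop("register must be 'IDS' or 'ADS'")
  }
  vowel <- normalize_vowel(as.character(vowel))
  if (any(!is.finite(median_f0)) || any(median_f0 <= 0)) {
    stop("median_f0 must be positive")
  }
  if (is.null(track) && (is.null(f1) || is.null(f2))) {
    stop("supply either `track` or both `f1` and `f2`")
  }
  out <- tibble::tibble(
    token_id = if (is.null(token_id)) paste0("tok", seq_len(n)) else as.character(token_id),
    speaker_id = as.character(speaker_id),
    register = register,
    vowel = vowel,
    median_f0 = as.numeric(median_f0)
  )
  if (!is.null(f1)) out$f1 <- as.numeric(f1)
  if (!is.null(f2)) out$f2 <- as.numeric(f2)
  if (!is.null(track)) out$track <- track
  out
}

#' Exclude vowel tokens with high fundamental frequency
#'
#' Formant estimation is unreliable at high f0, so tokens whose median f0
#' exceeds the threshold are excluded. The boundary is strict: a token at
#' exactly the threshold is kept. The partition is exhaustive and logged.
#'
#' @param tokens A vowel-token tibble with column `median_f0`.
#' @param threshold Exclusion bound in Hz (default 350).
#' @return List with `kept` and `excluded` token tibbles and a `log` tibble
#'   recording each excluded token id and its f0.
#' @examples
#' tok <- vowel_tokens("s1", "IDS", c("i", "i"), c(340, 360),
#'                     f1 = c(400, 410), f2 = c(2000, 2010))
#' exclude_high_f0(tok)$excluded$median_f0  # 360
#' @export
exclude_high_f0 <- function(tokens, threshold = 350) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("`threshold` must be a positive number")
  }
  stopifnot("median_f0" %in% names(tokens))
  out <- tokens$median_f0 > threshold
  log <- tibble::tibble(
    token_id = tokens$token_id[out],
    speaker_id = tokens$speaker_id[out],
    median_f0 = tokens$median_f0[out],
    reason = sprintf("median f0 %.1f Hz exceeds %g Hz", tokens$median_f0[out],
                     threshold)
  )
  list(kept = tokens[!out, , drop = FALSE],
       excluded = tokens[out, , drop = FALSE],
       log = log)
}

#' Mid-vowel windowed formant mean
#'
#' Averages F1 and F2 over the central portion of the vowel to reduce the
#' influence of coarticulated onsets and offsets. For the default fraction
#' 0.4 the window is the closed interval from 30% to 70% of the token's
#' duration; samples are selected by timestamp, not index. If no sample
#' falls inside the window the single sample nearest the temporal midpoint
#' is used.
#'
#' @param track A [formant_track()].
#' @param fraction Central fraction of the duration to keep, in (0, 1].
#' @return Named numeric vector `c(f1 = , f2 = )` in Hz.
#' @export
mid_window_mean <- function(track, fraction = 0.4) {
  if (is.null(track) || nrow(track) == 0) stop("empty formant track")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]")
  }
  t0 <- track$time[1]
  t1 <- track$time[nrow(track)]
  d <- t1 - t0
  lo <- t0 + (0.5 - fraction / 2) * d
  hi <- t0 + (0.5 + fraction / 2) * d
  inside <- track$time >= lo & track$time <= hi
  if (!any(inside)) {
    mid <- t0 + d / 2
    inside <- seq_len(nrow(track)) == which.min(abs(track$time - mid))
  }
  c(f1 = mean(track$f1[inside]), f2 = mean(track$f2[inside]))
}

#' Per-token point formant estimates
#'
#' Adds `f1`/`f2` columns from mid-window track averaging where a track is
#' present; tokens supplied with pre-averaged values pass through unchanged
#' and are flagged in `formant_source`.
#'
#' @param tokens Vowel-token tibble.
#' @param fraction Central window fraction, see [mid_window_mean()].
#' @return The token tibble with `f1`, `f2` and `formant_source` columns.
#' @export
extract_point_estimates <- function(tokens, fraction = 0.4) {
  has_track <- "track" %in% names(tokens)
  has_point <- all(c("f1", "f2") %in% names(tokens))
  if (!has_track && !has_point) {
    stop("tokens carry neither tracks nor point formant values")
  }
  if (!has_point) {
    tokens$f1 <- NA_real_
    tokens$f2 <- NA_real_
  }
  tokens$formant_source <- if (has_point) "point" else NA_character_
  if (has_track) {
    for (i in seq_len(nrow(tokens))) {
      tr <- tokens$track[[i]]
      if (!is.null(tr)) {
        est <- mid_window_mean(tr, fraction)
        tokens$f1[i] <- est[["f1"]]
        tokens$f2[i] <- est[["f2"]]
        tokens$formant_source[i] <- sprintf("track-mid%g", fraction)
      }
    }
  }
  tokens
}

#' Convert frequency from Hz to Bark
#'
#' Critical-band rate transform `z = 26.81 f / (1960 + f) - 0.53`, with the
#' standard corrections at the scale ends: `z + 0.15 (2 - z)` when `z < 2`
#' and `z + 0.22 (z - 20.1)` when `z > 20.1`. Strictly increasing in `f`.
#'
#' @param f Frequency in Hz, positive; vectorized.
#' @return Bark value(s).
#' @examples
#' hz_to_bark(1960)  # 12.875
#' @export
hz_to_bark <- function(f) {
  if (any(!is.finite(f)) || any(f <= 0)) stop("frequencies must be positive")
  z <- 26.81 * f / (1960 + f) - 0.53
  z <- ifelse(z < 2, z + 0.15 * (2 - z), z)
  z <- ifelse(z > 20.1, z + 0.22 * (z - 20.1), z)
  z
}

#' Per-speaker point-vowel means and vowel space area
#'
#' Averages each point vowel's per-token formant estimates for one speaker
#' and register, then computes the vowel space area. Token-level mid-window
#' means are taken first and then averaged unweighted across tokens. On the
#' Bark scale each token's Hz values are converted before averaging.
#'
#' @param tokens Vowel-token tibble (after f0 screening), single speaker and
#'   register; must contain all three point vowels.
#' @param speaker_id,register Selected from `tokens` when `NULL`.
#' @param scale `"hz"` or `"bark"`.
#' @param fraction Central window fraction for track tokens.
#' @return A `speaker_vsa`: speaker, register, scale, per-vowel `means`
#'   tibble (`vowel`, `f1`, `f2`, `n_tokens`) and `area` in Hz^2 or Bark^2.
#' @export
point_vowel_means <- function(tokens, speaker_id = NULL, register = NULL,
                              scale = c("hz", "bark"), fraction = 0.4) {
  scale <- match.arg(scale)
  if (!is.null(speaker_id)) tokens <- tokens[tokens$speaker_id == speaker_id, ]
  if (!is.null(register)) tokens <- tokens[tokens$register == register, ]
  if (nrow(tokens) == 0) stop("no tokens for the requested speaker/register")
  if (length(unique(tokens$speaker_id)) > 1 || length(unique(tokens$register)) > 1) {
    stop("tokens span more than one speaker or register; select one")
  }
  tokens <- extract_point_estimates(tokens, fraction)
  missing <- setdiff(point_vowels, unique(tokens$vowel))
  if (length(missing) > 0) {
    stop("no tokens for point vowel(s): ", paste(missing, collapse = ", "),
         " (speaker ", tokens$speaker_id[1], ", ", tokens$register[1], ")")
  }
  if (scale == "bark") {
    tokens$f1 <- hz_to_bark(tokens$f1)
    tokens$f2 <- hz_to_bark(tokens$f2)
  }
  means <- tokens |>
    dplyr::group_by(vowel = factor(.data$vowel, levels = point_vowels)) |>
    dplyr::summarise(f1 = mean(.data$f1), f2 = mean(.data$f2),
                     n_tokens = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(vowel = as.character(.data$vowel))
  out <- list(
    speaker_id = tokens$speaker_id[1],
    register = tokens$register[1],
    scale = scale,
    means = means,
    area = vsa(means)
  )
  class(out) <- "speaker_vsa"
  out
}

#' @export
print.speaker_vsa <- function(x, ...) {
  cat("<speaker_vsa> ", x$speaker_id, " ", x$register, " (", x$scale, "): area ",
      format(x$area, big.mark = ","), " ", if (x$scale == "hz") "Hz^2" else "Bark^2",
      "\n", sep = "")
  invisible(x)
}

#' Vowel space area of the point-vowel triangle
#'
#' Area of the triangle spanned by the mean (F1, F2) of /i/, /ɑ/ and /u/:
#' `ABS((iF1 (aF2 - uF2) + aF1 (uF2 - iF2) + uF1 (iF2 - aF2)) / 2)`.
#' Collinear means give area zero.
#'
#' @param means A data frame with columns `vowel` (containing "i", "ɑ" or
#'   "a", and "u"), `f1` and `f2`, or a `speaker_vsa` object.
#' @return Non-negative area in (scale unit)^2.
#' @examples
#' m <- data.frame(vowel = c("i", "a", "u"),
#'                 f1 = c(453, 656, 430), f2 = c(1972, 1383, 934))
#' vsa(m)  # 112130.5
#' @export
vsa <- function(means) {
  if (inherits(means, "speaker_vsa")) means <- means$means
  stopifnot(all(c("vowel", "f1", "f2") %in% names(means)))
  v <- normalize_vowel(as.character(means$vowel))
  if (anyDuplicated(v) || !setequal(v, point_vowels)) {
    stop("`means` must contain each point vowel exactly once")
  }
  i <- match("i", v); a <- match("ɑ", v); u <- match("u", v)
  abs(means$f1[i] * (means$f2[a] - means$f2[u]) +
      means$f1[a] * (means$f2[u] - means$f2[i]) +
      means$f1[u] * (means$f2[i] - means$f2[a])) / 2
}

#' Register difference in vowel space area
#'
#' Signed difference VSA(IDS) - VSA(ADS) for one speaker; negative values
#' (hypoarticulation in IDS) are preserved.
#'
#' @param ids,ads `speaker_vsa` objects for the same speaker on the same
#'   scale.
#' @return A `vsa_difference`: `speaker_id`, `vsa_ids`, `vsa_ads`,
#'   `difference`, `scale`.
#' @export
vsa_difference <- function(ids, ads) {
  stopifnot(inherits(ids, "speaker_vsa"), inherits(ads, "speaker_vsa"))
  if (ids$scale != ads$scale) {
    stop("scale mismatch: ", ids$scale, " vs ", ads$scale)
  }
  if (ids$speaker_id != ads$speaker_id) {
    stop("speaker mismatch: ", ids$speaker_id, " vs ", ads$speaker_id)
  }
  if (ids$register != "IDS" || ads$register != "ADS") {
    stop("`ids` must be the IDS estimate and `ads` the ADS estimate")
  }
  out <- list(speaker_id = ids$speaker_id,
              vsa_ids = ids$area,
              vsa_ads = ads$area,
              difference = ids$area - ads$area,
              scale = ids$scale)
  class(out) <- "vsa_difference"
  out
}

#' @export
print.vsa_difference <- function(x, ...) {
  cat("<vsa_difference> ", x$speaker_id, " (", x$scale, "): ",
      format(x$difference, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Per-speaker VSA table for both registers
#'
#' Full vowel-space arm of the pipeline: f0 screening, mid-window formant
#' extraction, per-register point-vowel means and areas, and the IDS - ADS
#' difference, for every speaker in the token table.
#'
#' @param tokens Vowel-token tibble covering both registers.
#' @param scale `"hz"` or `"bark"`.
#' @param f0_max f0 exclusion threshold in Hz.
#' @param fraction Central window fraction.
#' @return List with `table` (tibble: `speaker_id`, `vsa_ids`, `vsa_ads`,
#'   `difference`), `exclusions` (f0 screening log) and `scale`.
#' @export
speaker_vsa_table <- function(tokens, scale = c("hz", "bark"), f0_max = 350,
                              fraction = 0.4) {
  scale <- match.arg(scale)
  screened <- exclude_high_f0(tokens, f0_max)
  kept <- extract_point_estimates(screened$kept, fraction)
  if (scale == "bark") {
    kept$f1 <- hz_to_bark(kept$f1)
    kept$f2 <- hz_to_bark(kept$f2)
  }
  means <- kept |>
    dplyr::group_by(.data$speaker_id, .data$register, .data$vowel) |>
    dplyr::summarise(f1 = mean(.data$f1), f2 = mean(.data$f2),
                     .groups = "drop")
  cover <- means |>
    dplyr::group_by(.data$speaker_id, .data$register) |>
    dplyr::summarise(ok = dplyr::n() == 3, .groups = "drop")
  if (!all(cover$ok) ||
      !all(table(cover$speaker_id) == 2)) {
    bad <- unique(c(cover$speaker_id[!cover$ok],
                    names(which(table(cover$speaker_id) != 2))))
    stop("speaker(s) lacking all three point vowels in both registers: ",
         paste(bad, collapse = ", "))
  }
  areas <- vapply(split(means, paste(means$speaker_id, means$register,
                                     sep = "\r")),
                  vsa, numeric(1))
  key <- do.call(rbind, strsplit(names(areas), "\r", fixed = TRUE))
  wide <- tibble::tibble(speaker_id = key[, 1], register = key[, 2],
                         area = unname(areas))
  tab <- dplyr::inner_join(
    dplyr::filter(wide, .data$register == "IDS") |>
      dplyr::select("speaker_id", vsa_ids = "area"),
    dplyr::filter(wide, .data$register == "ADS") |>
      dplyr::select("speaker_id", vsa_ads = "area"),
    by = "speaker_id")
  tab$difference <- tab$vsa_ids - tab$vsa_ads
  tab <- tab[order(match(tab$speaker_id, unique(kept$speaker_id))), ]
  list(table = tab, exclusions = screened$log, scale = scale)
}
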
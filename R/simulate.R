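#' Simulation configuration for synthetic study data
#'
#' Defines the generating model for synthetic parent vowel tokens and infant
#' vocalization corpora. Parent acoustics are anchored to the group
#' descriptive statistics of the point vowels: ADS grand mean formants, with
#' per-vowel SDs split between a between-speaker and a within-speaker
#' (token) component. A speaker's IDS triangle is the speaker's ADS triangle
#' expanded linearly about its centroid by `ids_expansion`, so the true IDS
#' area is `ids_expansion^2` times the true ADS area. Median f0 straddles
#' the exclusion bound: each token exceeds it with probability
#' `exceed_rate`, drawn from truncated normals on either side. Tracks carry
#' linear coarticulation ramps at both edges so mid-vowel windowing is
#' exercised. Each infant's expected mean WCM-SE score is linearly linked to
#' the parent's true VSA difference with slope `beta_true`, and the
#' vocalization generator is calibrated so its analytic expected score
#' equals that target.
#'
#' @param n_dyads Number of parent-infant dyads.
#' @param ads_means ADS grand mean formants: tibble with `vowel`, `f1`, `f2`.
#' @param formant_sds Per-register, per-vowel token SDs (Hz): list with
#'   elements `IDS` and `ADS`, each a tibble `vowel`, `f1_sd`, `f2_sd`.
#' @param sd_split Share of total formant variance placed between speakers
#'   (the rest is within-speaker token noise).
#' @param noise_scale Multiplier on every formant SD; 0 gives noiseless
#'   speakers.
#' @param within_scale Additional multiplier on the within-speaker (token)
#'   SD only, leaving the between-speaker spread untouched; use it to dial
#'   measurement noise down without collapsing the between-dyad signal.
#' @param ids_expansion Linear expansion factor of the IDS triangle about
#'   the ADS triangle centroid (> 0).
#' @param tokens_per_vowel Named per-register integer vectors of tokens per
#'   point vowel.
#' @param f0 Per-register f0 model: `mean`, `sd` (Hz) below the threshold,
#'   `exceed_rate` (probability a token's median f0 exceeds `f0_threshold`).
#' @param f0_threshold The exclusion bound the f0 distribution straddles.
#' @param token_form `"track"` for sampled formant tracks, `"point"` for
#'   pre-averaged steady-state values.
#' @param track Track shape: `frame_step` and `duration_range` (s),
#'   `ramp_fraction` (edge fraction occupied by each coarticulation ramp),
#'   `ramp_depth` (how far the edge starts toward `neutral`), `neutral`
#'   (schwa-like F1/F2 target, Hz), `noise_sd` (per-sample jitter, Hz).
#' @param beta_true True slope linking expected mean WCM-SE to VSA
#'   difference (points per Hz^2).
#' @param intercept True intercept (points).
#' @param resid_sd Residual SD of the subject-level expected mean score.
#' @param n_vocalizations Vocalizations generated per infant.
#' @param feature_weights Named non-negative weights over the ten complexity
#'   features steering which parameters carry a calibrated target score.
#' @return A `sim_config` object.
#' @export
sim_config <- function(
    n_dyads = 19,
    ads_means = tibble::tibble(vowel = c("i", "ɑ", "u"),
                               f1 = c(472, 661, 473),
                               f2 = c(1904, 1307, 1032)),
    formant_sds = list(
      IDS = tibble::tibble(vowel = c("i", "ɑ", "u"),
                           f1_sd = c(88, 117, 90), f2_sd = c(305, 263, 195)),
      ADS = tibble::tibble(vowel = c("i", "ɑ", "u"),
                           f1_sd = c(81, 96, 75), f2_sd = c(272, 234, 229))),
    sd_split = 0.5,
    noise_scale = 1,
    within_scale = 1,
    ids_expansion = 1.36,
    tokens_per_vowel = list(IDS = c(i = 27, "ɑ" = 49, u = 12),
                            ADS = c(i = 15, "ɑ" = 35, u = 6)),
    f0 = list(IDS = list(mean = 240, sd = 40, exceed_rate = 0.10),
              ADS = list(mean = 200, sd = 30, exceed_rate = 0.02)),
    f0_threshold = 350,
    token_form = c("track", "point"),
    track = list(frame_step = 0.00625, duration_range = c(0.08, 0.25),
                 ramp_fraction = 0.25, ramp_depth = 0.5,
                 neutral = c(f1 = 500, f2 = 1500), noise_sd = 10),
    beta_true = 8.07e-6,
    intercept = 1.0,
    resid_sd = 0.42,
    n_vocalizations = 30,
    feature_weights = NULL) {
  token_form <- match.arg(token_form)
  if (n_dyads < 1) stop("`n_dyads` must be at least 1")
  if (ids_expansion <= 0) stop("`ids_expansion` must be positive")
  if (sd_split < 0 || sd_split > 1) stop("`sd_split` must be in [0, 1]")
  if (noise_scale < 0) stop("`noise_scale` must be non-negative")
  if (within_scale < 0) stop("`within_scale` must be non-negative")
  for (reg in c("IDS", "ADS")) {
    if (any(formant_sds[[reg]]$f1_sd < 0) || any(formant_sds[[reg]]$f2_sd < 0)) {
      stop("formant SDs must be non-negative")
    }
    er <- f0[[reg]]$exceed_rate
    if (er < 0 || er > 1) stop("f0 exceed_rate must be in [0, 1]")
  }
  if (resid_sd < 0) stop("`resid_sd` must be non-negative")
  if (is.null(feature_weights)) {
    feature_weights <- stats::setNames(rep(1, length(wcm_features)), wcm_features)
  }
  if (!setequal(names(feature_weights), wcm_features) || any(feature_weights < 0)) {
    stop("`feature_weights` must be non-negative and named over: ",
         paste(wcm_features, collapse = ", "))
  }
  ads_means$vowel <- normalize_vowel(ads_means$vowel)
  structure(list(
    n_dyads = n_dyads, ads_means = ads_means, formant_sds = formant_sds,
    sd_split = sd_split, noise_scale = noise_scale, within_scale = within_scale,
    ids_expansion = ids_expansion, tokens_per_vowel = tokens_per_vowel,
    f0 = f0, f0_threshold = f0_threshold, token_form = token_form,
    track = track, beta_true = beta_true, intercept = intercept,
    resid_sd = resid_sd, n_vocalizations = n_vocalizations,
    feature_weights = feature_weights[wcm_features]
  ), class = "sim_config")
}

# truncated normal via quantile inversion
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Expand a point-vowel triangle about its centroid
#'
#' @param means Tibble with `vowel`, `f1`, `f2` for the three point vowels.
#' @param factor Linear expansion factor; the area scales by `factor^2`.
#' @return Means tibble with scaled vertices, centroid unchanged.
#' @export
expand_triangle <- function(means, factor) {
  stopifnot(nrow(means) == 3, factor > 0)
  c1 <- mean(means$f1); c2 <- mean(means$f2)
  means$f1 <- c1 + factor * (means$f1 - c1)
  means$f2 <- c2 + factor * (means$f2 - c2)
  means
}

# Draw one speaker's true per-register point-vowel means.
simulate_speaker_means <- function(config) {
  ads <- config$ads_means
  sds <- config$formant_sds$ADS
  between <- sqrt(config$sd_split) * config$noise_scale
  ads$f1 <- ads$f1 + stats::rnorm(3, 0, between * sds$f1_sd[match(ads$vowel, sds$vowel)])
  ads$f2 <- ads$f2 + stats::rnorm(3, 0, between * sds$f2_sd[match(ads$vowel, sds$vowel)])
  list(ADS = ads, IDS = expand_triangle(ads, config$ids_expansion))
}

#' Simulate vowel tokens for one speaker and register
#'
#' Draws per-vowel steady-state formants around the speaker's true means
#' with the within-speaker token SD, a median f0 that exceeds the exclusion
#' bound at the configured rate, and (in track form) time-stamped formant
#' tracks with linear coarticulation ramps at both edges.
#'
#' @param config A [sim_config()].
#' @param speaker_id Speaker identifier.
#' @param register `"IDS"` or `"ADS"`.
#' @param speaker_means True means for this speaker and register (tibble
#'   `vowel`, `f1`, `f2`); drawn from the config when `NULL`.
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @return A [vowel_tokens()] tibble.
#' @export
simulate_tokens <- function(config, speaker_id, register = c("IDS", "ADS"),
                            speaker_means = NULL, seed = NULL) {
  register <- match.arg(register)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(speaker_means)) {
    speaker_means <- simulate_speaker_means(config)[[register]]
  }
  sds <- config$formant_sds[[register]]
  within <- sqrt(1 - config$sd_split) * config$noise_scale * config$within_scale
  counts <- config$tokens_per_vowel[[register]]
  counts <- counts[counts >= 1]
  f0m <- config$f0[[register]]
  thr <- config$f0_threshold

  vowel <- normalize_vowel(rep(names(counts), counts))
  n <- length(vowel)
  mi <- match(vowel, speaker_means$vowel)
  si <- match(vowel, normalize_vowel(sds$vowel))
  f1 <- pmax(stats::rnorm(n, speaker_means$f1[mi], within * sds$f1_sd[si]), 1)
  f2 <- pmax(stats::rnorm(n, speaker_means$f2[mi], within * sds$f2_sd[si]), 1)
  above <- stats::runif(n) < f0m$exceed_rate
  f0 <- numeric(n)
  f0[!above] <- rtrunc_norm(sum(!above), f0m$mean, f0m$sd, upper = thr)
  f0[above] <- rtrunc_norm(sum(above), thr + 50, 50, lower = thr + 0.5)

  tok <- tibble::tibble(
    token_id = sprintf("%s-%s-%03d", speaker_id, register, seq_len(n)),
    speaker_id = speaker_id, register = register, vowel = vowel,
    median_f0 = f0
  )
  if (config$token_form == "point") {
    tok$f1 <- f1
    tok$f2 <- f2
  } else {
    tok$track <- lapply(seq_len(n), function(i) {
      simulate_track(f1[i], f2[i], config$track)
    })
  }
  tok
}

# One formant track: linear edge ramps toward a neutral target, steady
# centre, optional per-sample jitter.
simulate_track <- function(steady_f1, steady_f2, tr) {
  dur <- stats::runif(1, tr$duration_range[1], tr$duration_range[2])
  times <- seq(0, dur, by = tr$frame_step)
  if (length(times) < 3) times <- seq(0, dur, length.out = 3)
  rel <- times / dur
  edge1 <- steady_f1 + tr$ramp_depth * (tr$neutral[["f1"]] - steady_f1)
  edge2 <- steady_f2 + tr$ramp_depth * (tr$neutral[["f2"]] - steady_f2)
  shape <- function(rel, edge, steady) {
    r <- tr$ramp_fraction
    y <- rep(steady, length(rel))
    if (r > 0) {
      on <- rel < r
      off <- rel > 1 - r
      y[on] <- edge + (steady - edge) * rel[on] / r
      y[off] <- steady + (edge - steady) * (rel[off] - (1 - r)) / r
    }
    y
  }
  f1 <- shape(rel, edge1, steady_f1) + stats::rnorm(length(rel), 0, tr$noise_sd)
  f2 <- shape(rel, edge2, steady_f2) + stats::rnorm(length(rel), 0, tr$noise_sd)
  formant_track(times, pmax(f1, 1), pmax(f2, 1))
}

# ---- vocalization generator ------------------------------------------------

wcm_features <- c("tri", "stress", "final", "cluster",
                  "velar", "liquid", "fricative", "voiced_fricative",
                  "trill", "lfrv")

# points a single occurrence of each sound-class feature earns ([v] is both a
# fricative and a voiced fricative, a trill earns 3)
wcm_class_values <- c(velar = 1, liquid = 1, fricative = 1,
                      voiced_fricative = 2, trill = 3, lfrv = 1)

class_syllables <- c(velar = "ka", liquid = "la", fricative = "fa",
                     voiced_fricative = "va", trill = "ra", lfrv = "møː")

#' Analytic expected WCM-SE score of the vocalization generator
#'
#' The generator builds each vocalization from a zero-scoring base syllable
#' plus independent Bernoulli complexity features: one appended syllable per
#' sound-class feature, two extra syllables for the trisyllabicity feature,
#' an appended stressed syllable, an onset cluster, and a final consonant.
#' The expected score is available in closed form; the only non-linear term
#' is the more-than-two-syllables point.
#'
#' @param p Named probability vector over the features `tri`, `stress`,
#'   `final`, `cluster`, `velar`, `liquid`, `fricative`,
#'   `voiced_fricative`, `trill`, `lfrv`.
#' @return Expected WCM-SE score (points).
#' @export
expected_wcm_se <- function(p) {
  stopifnot(setequal(names(p), wcm_features), all(p >= 0), all(p <= 1))
  pc <- p[names(wcm_class_values)]
  # syllable count = 1 + #class features + 2*tri + stress
  p_k0 <- prod(1 - pc)
  p_k1 <- sum(vapply(seq_along(pc), function(j) {
    pc[j] * prod(1 - pc[-j])
  }, numeric(1)))
  p_poly <- 1 - (1 - p[["tri"]]) * (p_k0 + p_k1 * (1 - p[["stress"]]))
  unname(p_poly + p[["stress"]] + p[["final"]] + p[["cluster"]] +
           sum(pc * wcm_class_values))
}

# maximum expected score under weights w (features with zero weight stay off)
max_expected_wcm_se <- function(w) {
  p <- stats::setNames(as.numeric(w > 0), names(w))
  expected_wcm_se(p)
}

#' Calibrate feature probabilities to a target expected score
#'
#' Scales the configured feature weights by a common factor (capping each
#' probability at 1) until the analytic expected WCM-SE score equals the
#' target.
#'
#' @param target Target expected score (points, >= 0).
#' @param weights Named non-negative feature weights.
#' @return Named probability vector with
#'   `expected_wcm_se(p) == target` (to numerical tolerance).
#' @export
calibrate_wcm_probs <- function(target, weights) {
  stopifnot(setequal(names(weights), wcm_features), all(weights >= 0))
  w <- weights[wcm_features]
  if (target < 0) stop("target expected score must be non-negative")
  if (all(w == 0)) {
    if (target > 0) stop("target ", target, " unreachable: all weights are zero")
    return(stats::setNames(rep(0, length(w)), names(w)))
  }
  emax <- max_expected_wcm_se(w)
  if (target > emax + 1e-9) {
    stop("target expected score ", target, " unreachable; maximum under these ",
         "weights is ", emax)
  }
  pfun <- function(theta) pmin(theta * w, 1)
  theta_max <- max(1 / w[w > 0])
  if (target == 0) return(pfun(0))
  root <- stats::uniroot(function(th) expected_wcm_se(pfun(th)) - target,
                         lower = 0, upper = theta_max, tol = 1e-12)
  pfun(root$root)
}

# render one feature pattern (named 0/1 vector) as a transcription string
render_vocalization <- function(x) {
  syls <- if (x[["cluster"]] == 1) "pma" else "ma"
  for (cl in names(class_syllables)) {
    if (x[[cl]] == 1) syls <- c(syls, class_syllables[[cl]])
  }
  if (x[["tri"]] == 1) syls <- c(syls, "ma", "ma")
  if (x[["stress"]] == 1) syls <- c(syls, "ˈma")
  if (x[["final"]] == 1) syls[length(syls)] <- paste0(syls[length(syls)], "p")
  paste0(syls, collapse = ".")
}

# analytic score of a feature pattern, from the parameter point values
pattern_score <- function(x) {
  n_syl <- 1 + sum(x[names(wcm_class_values)]) + 2 * x[["tri"]] + x[["stress"]]
  unname((n_syl > 2) + x[["stress"]] + x[["final"]] + x[["cluster"]] +
           sum(x[names(wcm_class_values)] * wcm_class_values))
}

#' Simulate infant vocalization transcriptions with a target expected score
#'
#' Draws independent Bernoulli complexity features per vocalization, with
#' probabilities calibrated so the analytic expected WCM-SE score equals
#' `target_expected_score`, and renders each draw as a transcription string
#' over the packaged inventory.
#'
#' @param target_expected_score Target expected score in points; 0 yields
#'   bare consonant-vowel syllables that score 0.
#' @param n Number of vocalizations.
#' @param config A [sim_config()] (supplies the feature weights).
#' @param seed Optional integer seed; `NULL` continues the RNG stream.
#' @return Character vector of `n` transcription strings.
#' @examples
#' simulate_vocalizations(0, 2, seed = 1)       # "ma" "ma"
#' @export
simulate_vocalizations <- function(target_expected_score, n,
                                   config = sim_config(), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  p <- calibrate_wcm_probs(target_expected_score, config$feature_weights)
  draws <- matrix(stats::rbinom(n * length(p), 1, rep(p, each = n)),
                  nrow = n, dimnames = list(NULL, names(p)))
  code <- draws %*% 2^(seq_along(p) - 1)
  out <- character(n)
  for (cd in unique(code)) {
    i <- which(code == cd)
    out[i] <- render_vocalization(draws[i[1], ])
  }
  out
}

#' Simulate a full synthetic study
#'
#' Generates, per dyad, true speaker vowel triangles (ADS drawn around the
#' configured anchors, IDS a centroid expansion of it), vowel tokens for
#' both registers, the true vowel space areas and their difference, an
#' expected mean WCM-SE score linearly linked to the true VSA difference
#' with slope `beta_true` and residual noise, and an infant corpus drawn at
#' that expected score. Expected scores falling outside the generator's
#' reachable range are clamped and logged in the truth table.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for the whole dataset; `NULL` continues the
#'   current RNG stream.
#' @return A `synthetic_dataset`: `tokens` (vowel-token tibble over all
#'   dyads and registers), `transcriptions` (`subject_id`,
#'   `vocalization_id`, `transcription`), and `truth` (per-dyad true areas,
#'   difference, and expected mean score).
#' @export
simulate_study <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  emax <- max_expected_wcm_se(config$feature_weights)
  tokens <- vector("list", config$n_dyads)
  trans <- vector("list", config$n_dyads)
  truth <- vector("list", config$n_dyads)
  for (i in seq_len(config$n_dyads)) {
    sp <- sprintf("dyad%02d", i)
    mu <- simulate_speaker_means(config)
    area_ads <- vsa(mu$ADS)
    area_ids <- vsa(mu$IDS)
    diff_true <- area_ids - area_ads
    target <- config$intercept + config$beta_true * diff_true +
      stats::rnorm(1, 0, config$resid_sd)
    clamped <- target < 0 || target > emax
    target <- min(max(target, 0), emax)
    tokens[[i]] <- dplyr::bind_rows(
      simulate_tokens(config, sp, "IDS", speaker_means = mu$IDS),
      simulate_tokens(config, sp, "ADS", speaker_means = mu$ADS))
    vocs <- simulate_vocalizations(target, config$n_vocalizations, config)
    trans[[i]] <- tibble::tibble(
      subject_id = sp,
      vocalization_id = sprintf("%s-v%03d", sp, seq_along(vocs)),
      transcription = vocs)
    truth[[i]] <- tibble::tibble(
      speaker_id = sp, vsa_ads_true = area_ads, vsa_ids_true = area_ids,
      difference_true = diff_true, expected_wcm = target, clamped = clamped)
  }
  out <- list(tokens = dplyr::bind_rows(tokens),
              transcriptions = dplyr::bind_rows(trans),
              truth = dplyr::bind_rows(truth),
              config = config)
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$truth), " dyads, ", nrow(x$tokens),
      " vowel tokens, ", nrow(x$transcriptions), " vocalizations\n", sep = "")
  invisible(x)
}
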
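#' WCM-SE complexity parameters
#'
#' The ten complexity parameters of the Word Complexity Measure for Swedish,
#' in three domains: word patterns (more than two syllables; non-initial
#' primary stress), syllable structures (word-final consonant; consonant
#' cluster), and sound classes (velar, liquid, fricative, voiced fricative,
#' trill, long front rounded vowel). Word-pattern and word-final parameters
#' score at most one point per vocalization; cluster and sound-class
#' parameters score per occurrence; a trill earns three points per
#' occurrence, every other parameter one.
#'
#' @return Named integer vector of points per single occurrence.
#' @export
wcm_parameters <- function() {
  c("polysyllabic" = 1L,
    "non-initial-stress" = 1L,
    "word-final-consonant" = 1L,
    "consonant-cluster" = 1L,
    "velar" = 1L,
    "liquid" = 1L,
    "fricative" = 1L,
    "voiced-fricative" = 1L,
    "trill" = 3L,
    "long-front-rounded-vowel" = 1L)
}

consonant_like <- c("consonant", "unknown-consonant")

#' Score one vocalization with the WCM-SE
#'
#' Word-pattern points: +1 if the vocalization has more than two syllables;
#' +1 if a marked primary stress falls on a non-initial syllable. Syllable
#' structure: +1 if the final phone is a consonant (including the `C` cover
#' symbol); +1 per consonant cluster, defined as a maximal run of two or
#' more consecutive consonant-like phones, ignoring syllable boundaries
#' (an indeterminate segment breaks a run). Sound classes: each phone earns
#' the points of every class it belongs to; trills earn three points per
#' occurrence; the long-front-rounded-vowel class requires the length mark.
#'
#' @param v A `vocalization` from [parse_transcription()].
#' @param inventory Inventory supplying sound-class membership.
#' @param cluster_scope `"vocalization"` (default) counts clusters across
#'   syllable boundaries; `"syllable"` counts only tautosyllabic runs.
#' @return A `wcm_score`: `total` (non-negative integer) and the named
#'   integer `breakdown` over the ten [wcm_parameters()];
#'   `total == sum(breakdown)` always holds.
#' @examples
#' score_vocalization(parse_transcription("e.le.ˈfant"))$total  # 6
#' score_vocalization(parse_transcription("ˈsku:"))$total       # 3
#' score_vocalization(parse_transcription("màma"))$total        # 0
#' @export
score_vocalization <- function(v, inventory = default_inventory(),
                               cluster_scope = c("vocalization", "syllable")) {
  stopifnot(inherits(v, "vocalization"))
  cluster_scope <- match.arg(cluster_scope)
  idx <- inventory_index(inventory)

  breakdown <- wcm_parameters()
  breakdown[] <- 0L

  breakdown["polysyllabic"] <- as.integer(v$n_syllables > 2L)
  breakdown["non-initial-stress"] <- as.integer(!is.na(v$stressed) && v$stressed > 1L)

  n <- length(v$symbol)
  breakdown["word-final-consonant"] <- as.integer(v$category[n] %in% consonant_like)

  is_cons <- v$category %in% consonant_like
  if (cluster_scope == "vocalization") {
    runs <- rle(is_cons)
    breakdown["consonant-cluster"] <- sum(runs$values & runs$lengths >= 2L)
  } else {
    breakdown["consonant-cluster"] <- sum(vapply(seq_len(v$n_syllables), function(s) {
      runs <- rle(is_cons[v$syllable == s])
      sum(runs$values & runs$lengths >= 2L)
    }, integer(1)))
  }

  for (i in seq_len(n)) {
    cls <- phone_classes(v$base[i], v$long[i], idx)
    for (cl in cls) breakdown[cl] <- breakdown[cl] + 1L
  }
  breakdown["trill"] <- breakdown["trill"] * 3L

  out <- list(total = sum(breakdown), breakdown = breakdown, raw = v$raw)
  class(out) <- "wcm_score"
  out
}

#' @export
print.wcm_score <- function(x, ...) {
  cat("<wcm_score> ", x$raw, ": total ", x$total, "\n", sep = "")
  nz <- x$breakdown[x$breakdown > 0]
  if (length(nz) > 0) {
    cat("  ", paste0(names(nz), "=", nz, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Score a corpus of vocalizations
#'
#' Order-preserving map of [score_vocalization()] over parsed vocalizations
#' or raw transcription strings. Strings are parsed first; duplicate strings
#' are scored once and reused, so large generated corpora score quickly.
#'
#' @param vocalizations A list of `vocalization` objects or a character
#'   vector of transcriptions.
#' @param inventory,cluster_scope Passed to [score_vocalization()].
#' @return A tibble with one row per vocalization: `transcription`, `total`,
#'   and one column per WCM-SE parameter.
#' @export
score_corpus <- function(vocalizations, inventory = default_inventory(),
                         cluster_scope = "vocalization") {
  if (is.character(vocalizations)) {
    uniq <- unique(vocalizations)
    scores <- lapply(uniq, function(s) {
      score_vocalization(parse_transcription(s, inventory = inventory),
                         inventory = inventory, cluster_scope = cluster_scope)
    })
    pos <- match(vocalizations, uniq)
    raws <- vocalizations
  } else {
    if (length(vocalizations) > 0 &&
        !all(vapply(vocalizations, inherits, logical(1), "vocalization"))) {
      stop("`vocalizations` must be vocalization objects or strings")
    }
    scores <- lapply(vocalizations, score_vocalization, inventory = inventory,
                     cluster_scope = cluster_scope)
    pos <- seq_along(scores)
    raws <- vapply(vocalizations, function(v) v$raw, character(1))
  }
  if (length(pos) == 0) {
    cols <- c(list(transcription = character(0), total = integer(0)),
              stats::setNames(rep(list(integer(0)), length(wcm_parameters())),
                              names(wcm_parameters())))
    return(tibble::as_tibble(cols))
  }
  totals <- vapply(scores, `[[`, integer(1), "total")
  brk <- do.call(rbind, lapply(scores, `[[`, "breakdown"))
  out <- tibble::as_tibble(cbind(
    tibble::tibble(transcription = raws, total = totals[pos]),
    brk[pos, , drop = FALSE]
  ))
  out
}

#' Per-subject mean WCM-SE score
#'
#' @param subject_id Subject identifier.
#' @param scores A list of `wcm_score` objects, or a numeric vector of
#'   totals, for that subject's vocalizations.
#' @return A `subject_wcm_summary`: `subject_id`, `n_vocalizations`,
#'   `mean_score`.
#' @examples
#' subject_mean("s1", c(6, 3, 0))$mean_score  # 3
#' @export
subject_mean <- function(subject_id, scores) {
  if (length(scores) == 0) stop("no scores for subject ", subject_id)
  totals <- if (is.numeric(scores)) {
    scores
  } else {
    vapply(scores, function(s) {
      if (!inherits(s, "wcm_score")) stop("`scores` must be wcm_score objects")
      as.numeric(s$total)
    }, numeric(1))
  }
  out <- list(subject_id = subject_id,
              n_vocalizations = length(totals),
              mean_score = mean(totals))
  class(out) <- "subject_wcm_summary"
  out
}

#' @export
print.subject_wcm_summary <- function(x, ...) {
  cat("<subject_wcm_summary> ", x$subject_id, ": mean ",
      format(x$mean_score, digits = 4), " over ", x$n_vocalizations,
      " vocalizations\n", sep = "")
  invisible(x)
}

#' Subject-level WCM-SE summary table
#'
#' Parses and scores a transcription table and averages per subject.
#'
#' @param transcriptions A tibble/data.frame with columns `subject_id` and
#'   `transcription` (one vocalization per row).
#' @param inventory Passed through to the parser and scorer.
#' @return Tibble with `subject_id`, `n_vocalizations`, `mean_score`.
#' @export
subject_wcm_table <- function(transcriptions, inventory = default_inventory()) {
  stopifnot(all(c("subject_id", "transcription") %in% names(transcriptions)))
  scored <- score_corpus(transcriptions$transcription, inventory = inventory)
  tibble::tibble(subject_id = transcriptions$subject_id, total = scored$total) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_vocalizations = dplyr::n(),
                     mean_score = mean(.data$total),
                     .groups = "drop")
}
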
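#' Read a vowel token table from CSV
#'
#' Expected header: `speaker_id`, `register`, `vowel`, `median_f0`, then
#' either point estimates `f1`, `f2` (Hz) or a `track_file` column naming a
#' per-token CSV (`time,f1,f2[,f0]`) resolved relative to the table's
#' directory. Invalid rows (unknown register or vowel label, non-positive
#' or non-numeric frequencies, unreadable track file) are rejected
#' individually with row-numbered messages rather than failing the whole
#' read.
#'
#' @param path Path to the token CSV.
#' @return List with `tokens` (validated [vowel_tokens()] tibble) and
#'   `rejected` (tibble of `row`, `message`).
#' @export
read_token_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) stop("token table is empty: ", path)
  required <- c("speaker_id", "register", "vowel", "median_f0")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("token table lacks column(s): ", paste(missing, collapse = ", "))
  }
  has_point <- all(c("f1", "f2") %in% names(raw))
  has_track <- "track_file" %in% names(raw)
  if (!has_point && !has_track) {
    stop("token table needs either `f1` and `f2` columns or a `track_file` column")
  }
  base_dir <- dirname(path)

  msgs <- character(nrow(raw))
  check <- function(cond, i, msg) {
    if (!cond && !nzchar(msgs[i])) msgs[i] <<- msg
    cond
  }
  tracks <- if (has_track) vector("list", nrow(raw)) else NULL
  for (i in seq_len(nrow(raw))) {
    check(raw$register[i] %in% c("IDS", "ADS"), i,
          paste0("unknown register '", raw$register[i], "'"))
    check(raw$vowel[i] %in% c("i", "ɑ", "a", "u"), i,
          paste0("unknown vowel label '", raw$vowel[i], "'"))
    f0ok <- suppressWarnings(!is.na(as.numeric(raw$median_f0[i])) &&
                               as.numeric(raw$median_f0[i]) > 0)
    check(f0ok, i, "median_f0 must be a positive number")
    if (has_point) {
      ok <- suppressWarnings(all(is.finite(as.numeric(c(raw$f1[i], raw$f2[i])))) &&
                               all(as.numeric(c(raw$f1[i], raw$f2[i])) > 0))
      check(ok, i, "formant values must be positive numbers")
    } else if (!nzchar(msgs[i])) {
      tf <- file.path(base_dir, raw$track_file[i])
      tr <- tryCatch({
        td <- readr::read_csv(tf, show_col_types = FALSE, progress = FALSE)
        formant_track(td$time, td$f1, td$f2,
                      f0 = if ("f0" %in% names(td)) td$f0 else NULL)
      }, error = function(e) conditionMessage(e))
      if (is.character(tr)) {
        msgs[i] <- paste0("track file '", raw$track_file[i], "': ", tr)
      } else {
        tracks[[i]] <- tr
      }
    }
  }
  ok <- !nzchar(msgs)
  rejected <- tibble::tibble(row = which(!ok), message = msgs[!ok])
  if (!any(ok)) stop("no valid rows in token table: ", path)
  kept <- raw[ok, , drop = FALSE]
  tokens <- vowel_tokens(
    speaker_id = kept$speaker_id,
    register = kept$register,
    vowel = kept$vowel,
    median_f0 = as.numeric(kept$median_f0),
    f1 = if (has_point) as.numeric(kept$f1) else NULL,
    f2 = if (has_point) as.numeric(kept$f2) else NULL,
    track = if (has_track) tracks[ok] else NULL,
    token_id = if ("token_id" %in% names(kept)) kept$token_id else NULL
  )
  list(tokens = tokens, rejected = rejected)
}

#' Write a vowel token table to CSV
#'
#' Track-form tokens are written as one CSV per track under `tracks_dir`
#' with a `track_file` column referencing them; point-form tokens are
#' written inline.
#'
#' @param tokens A [vowel_tokens()] tibble.
#' @param path Output CSV path.
#' @param tracks_dir Directory (relative to `path`) for per-token track
#'   CSVs; required when `tokens` carries tracks.
#' @return `path`, invisibly.
#' @export
write_token_table <- function(tokens, path, tracks_dir = "tracks") {
  out <- tokens
  if ("track" %in% names(tokens)) {
    dir.create(file.path(dirname(path), tracks_dir), showWarnings = FALSE,
               recursive = TRUE)
    files <- file.path(tracks_dir, paste0(tokens$token_id, ".csv"))
    for (i in seq_len(nrow(tokens))) {
      readr::write_csv(tokens$track[[i]], file.path(dirname(path), files[i]),
                       progress = FALSE)
    }
    out$track <- NULL
    out$track_file <- files
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read infant vocalization transcriptions
#'
#' Tab-separated input with columns `subject_id`, `transcription` and
#' optionally `vocalization_id`. Each row is parsed through
#' [parse_transcription()]; rows that fail to parse are collected with
#' their error messages instead of aborting the read.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param inventory A [phone_inventory()].
#' @return List with `transcriptions` (tibble `subject_id`,
#'   `vocalization_id`, `transcription`, plus the list-column
#'   `vocalization` of parsed objects) and `errors` (tibble `row`,
#'   `subject_id`, `transcription`, `message`).
#' @export
read_transcriptions <- function(path, inventory = default_inventory()) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "transcription")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("transcription table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"vocalization_id" %in% names(raw)) {
    raw$vocalization_id <- sprintf("v%04d", seq_len(nrow(raw)))
  }
  parsed <- lapply(seq_len(nrow(raw)), function(i) {
    tryCatch(parse_transcription(raw$transcription[i], inventory = inventory,
                                 subject_id = raw$subject_id[i]),
             error = function(e) conditionMessage(e))
  })
  failed <- vapply(parsed, is.character, logical(1))
  errors <- tibble::tibble(
    row = which(failed),
    subject_id = raw$subject_id[failed],
    transcription = raw$transcription[failed],
    message = unlist(parsed[failed], use.names = FALSE) %||% character(0)
  )
  ok <- raw[!failed, c("subject_id", "vocalization_id", "transcription")]
  ok$vocalization <- parsed[!failed]
  list(transcriptions = ok, errors = errors)
}

#' Read one interval tier from a Praat TextGrid
#'
#' Minimal reader for the long ("ooTextFile") TextGrid format: extracts the
#' labelled intervals of the named IntervalTier. Empty labels are dropped.
#'
#' @param path Path to a TextGrid file.
#' @param tier Tier name; defaults to the first interval tier.
#' @return Tibble with `xmin`, `xmax`, `text`.
#' @export
read_textgrid_tier <- function(path, tier = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  grab <- function(pat, x) sub(paste0(".*", pat, "\\s*=\\s*"), "", x)
  name_lines <- grep("name\\s*=", lines)
  if (length(name_lines) == 0) stop("no tiers found in TextGrid: ", path)
  tier_names <- gsub("\"", "", grab("name", lines[name_lines]))
  pick <- if (is.null(tier)) 1L else match(tier, tier_names)
  if (is.na(pick)) {
    stop("tier '", tier, "' not found; available: ",
         paste(tier_names, collapse = ", "))
  }
  from <- name_lines[pick]
  to <- if (pick < length(name_lines)) name_lines[pick + 1] - 1 else length(lines)
  chunk <- lines[from:to]
  xmins <- as.numeric(grab("xmin", chunk[grep("xmin\\s*=", chunk)]))
  xmaxs <- as.numeric(grab("xmax", chunk[grep("xmax\\s*=", chunk)]))
  texts <- gsub("^\"|\"$", "", grab("text", chunk[grep("text\\s*=", chunk)]))
  # the first xmin/xmax pair describes the tier itself, not an interval
  n <- length(texts)
  xmins <- utils::tail(xmins, n)
  xmaxs <- utils::tail(xmaxs, n)
  keep <- nzchar(trimws(texts))
  tibble::tibble(xmin = xmins[keep], xmax = xmaxs[keep], text = trimws(texts[keep]))
}

#' Read one annotation tier from an ELAN EAF file
#'
#' Extracts alignable annotations (start, end, value) from the named tier;
#' empty annotation values are dropped.
#'
#' @param path Path to an .eaf XML file.
#' @param tier `TIER_ID`; defaults to the first tier.
#' @return Tibble with `start`, `end` (seconds), `text`.
#' @export
read_eaf_tier <- function(path, tier = NULL) {
  doc <- xml2::read_xml(path)
  slots <- xml2::xml_find_all(doc, ".//TIME_ORDER/TIME_SLOT")
  slot_ms <- stats::setNames(
    as.numeric(xml2::xml_attr(slots, "TIME_VALUE")),
    xml2::xml_attr(slots, "TIME_SLOT_ID"))
  tiers <- xml2::xml_find_all(doc, ".//TIER")
  if (length(tiers) == 0) stop("no tiers found in EAF: ", path)
  ids <- xml2::xml_attr(tiers, "TIER_ID")
  pick <- if (is.null(tier)) 1L else match(tier, ids)
  if (is.na(pick)) {
    stop("tier '", tier, "' not found; available: ", paste(ids, collapse = ", "))
  }
  anns <- xml2::xml_find_all(tiers[[pick]], ".//ALIGNABLE_ANNOTATION")
  text <- trimws(xml2::xml_text(xml2::xml_find_first(anns, "./ANNOTATION_VALUE")))
  start <- slot_ms[xml2::xml_attr(anns, "TIME_SLOT_REF1")] / 1000
  end <- slot_ms[xml2::xml_attr(anns, "TIME_SLOT_REF2")] / 1000
  keep <- nzchar(text)
  tibble::tibble(start = unname(start[keep]), end = unname(end[keep]),
                 text = text[keep])
}

#' Annotation tier to transcription table
#'
#' Maps one annotation per interval to one vocalization row, so TextGrid
#' and EAF tiers feed the same pipeline as TSV input.
#'
#' @param annotations Tibble with a `text` column (from
#'   [read_textgrid_tier()] or [read_eaf_tier()]).
#' @param subject_id Subject the tier belongs to.
#' @return Tibble with `subject_id`, `vocalization_id`, `transcription`.
#' @export
tier_to_transcriptions <- function(annotations, subject_id) {
  tibble::tibble(
    subject_id = subject_id,
    vocalization_id = sprintf("%s-v%04d", subject_id, seq_len(nrow(annotations))),
    transcription = annotations$text
  )
}

# study_result -> plain nested list with deterministic key order
result_to_list <- function(result) {
  stopifnot(inherits(result, "study_result"))
  num <- function(x) unname(as.numeric(x))
  paired_list <- function(p) list(
    t = num(p$t), df = as.integer(p$df), p = num(p$p),
    mean_ids = num(p$mean_a), sd_ids = num(p$sd_a),
    mean_ads = num(p$mean_b), sd_ads = num(p$sd_b),
    mean_difference = num(p$mean_difference),
    sd_difference = num(p$sd_difference), n = as.integer(p$n),
    p_display = sprintf("%.3f", p$p))
  reg_list <- function(r) list(
    beta = num(r$beta), intercept = num(r$intercept), F = num(r$F),
    df = as.integer(r$df), r_squared = num(r$r_squared), p = num(r$p),
    n = as.integer(r$n), p_display = sprintf("%.3f", r$p))
  scales <- result$config$scales
  list(
    config = list(
      f0_max = result$config$f0_max,
      window_fraction = result$config$window_fraction,
      scales = as.list(scales),
      outlier_policy = result$config$outlier$type,
      predicted_delta = result$config$predicted_delta),
    paired = lapply(result$paired[scales], paired_list),
    regression = lapply(result$regression[scales], reg_list),
    predicted_increase = list(value = num(result$predicted$value),
                              display = result$predicted$display),
    vsa = lapply(result$vsa[scales], function(v) {
      lapply(split(v$table, seq_len(nrow(v$table))), function(r) {
        list(speaker_id = r$speaker_id, vsa_ids = num(r$vsa_ids),
             vsa_ads = num(r$vsa_ads), difference = num(r$difference))
      }) |> unname()
    }),
    subject_scores = lapply(split(result$subject_scores,
                                  seq_len(nrow(result$subject_scores))),
                            function(r) list(
                              subject_id = r$subject_id,
                              n_vocalizations = as.integer(r$n_vocalizations),
                              mean_score = num(r$mean_score))) |> unname(),
    excluded_subjects = lapply(split(result$excluded_subjects,
                                     seq_len(nrow(result$excluded_subjects))),
                               function(r) list(
                                 subject_id = r$subject_id,
                                 mean_score = num(r$mean_score),
                                 reason = r$reason)) |> unname(),
    audit = result$audit
  )
}

#' Write a study report
#'
#' JSON output is lossless (full numeric precision plus display-rounded
#' fields) with a fixed key order, so identical inputs, configuration and
#' seed produce byte-identical reports. The CSV variant writes one row per
#' subject followed by a commented summary block.
#'
#' @param result A `study_result` from [run_study()].
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  lst <- result_to_list(result)
  if (format == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE, na = "null")
  } else {
    primary <- result$config$scales[1]
    per_subject <- dplyr::left_join(
      result$vsa[[primary]]$table,
      result$subject_scores,
      by = c(speaker_id = "subject_id"))
    per_subject$excluded <- per_subject$speaker_id %in%
      result$excluded_subjects$subject_id
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.csv(per_subject, con, row.names = FALSE)
    p <- result$paired[[primary]]
    r <- result$regression[[primary]]
    writeLines(c(
      sprintf("# paired t(%d) = %.4f, p = %.6g", p$df, p$t, p$p),
      sprintf("# regression F(%d,%d) = %.4f, beta = %.6g, R2 = %.4f, p = %.6g",
              r$df[1], r$df[2], r$F, r$beta, r$r_squared, r$p),
      sprintf("# predicted increase per %g: %s", result$config$predicted_delta,
              result$predicted$display)), con)
  }
  invisible(path)
}

#' Read a JSON study report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return Nested list mirroring the report structure.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
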
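#' Parse an IPA-like transcription of an infant vocalization
#'
#' Transcriptions use Unicode IPA phone symbols with "." as syllable
#' boundary, the IPA stress mark before a syllable for primary stress, and
#' the IPA length mark attached to the preceding phone. Unrecognizable
#' segments are transcribed "C" (consonant-like), "V" (vowel-like) or the
#' indeterminate square. Two stress notations are accepted and normalized:
#' an explicit stress mark (ASCII apostrophe is an alias) before the
#' syllable, or a grave/acute accent diacritic on the syllable's vowel;
#' ASCII ":" is an alias for the length mark.
#'
#' If the string contains no syllable boundaries and more than one vowel
#' nucleus, it is syllabified deterministically by vowel nuclei with onset
#' maximization: every intervocalic phone that is not itself a nucleus is
#' assigned to the onset of the following syllable, and phones after the
#' last nucleus close the final syllable.
#'
#' @param text A single non-empty transcription string.
#' @param inventory A [phone_inventory()]; defaults to the packaged Swedish
#'   inventory.
#' @param subject_id Optional subject identifier carried on the result.
#' @return A `vocalization` object: phone-level vectors (`syllable`,
#'   `symbol`, `base`, `category`, `long`), the 1-based `stressed` syllable
#'   index (`NA` when unmarked), `n_syllables`, and the source string `raw`.
#'   `format()` renders the canonical form (stress as the IPA mark, length
#'   as the IPA length sign, boundaries as ".").
#' @examples
#' v <- parse_transcription("e.le.ˈfant")
#' count_syllables(v)
#' format(v)
#' @export
parse_transcription <- function(text, inventory = default_inventory(),
                                subject_id = NA_character_) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    stop("`text` must be a single string")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("empty transcription")
  idx <- inventory_index(inventory)

  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  chars <- unlist(lapply(chars, normalize_char), use.names = FALSE)

  # phone-level accumulators
  symbol <- character(0); category <- character(0); long <- logical(0)
  syllable <- integer(0)
  # per-syllable bookkeeping
  syl_stressed <- logical(0)
  stress_phone <- integer(0)   # phone index (global) carrying an accent, 0 if none
  cur <- 0L                    # phones in current syllable
  cur_syl <- 1L
  cur_stressed <- FALSE
  cur_accent_phone <- 0L
  pending_stress <- FALSE
  explicit_boundary <- FALSE
  n_stress_marks <- 0L

  close_syllable <- function(pos) {
    if (cur == 0L) {
      stop("empty syllable before position ", pos, " in '", text, "'")
    }
    syl_stressed[cur_syl] <<- cur_stressed
    stress_phone[cur_syl] <<- cur_accent_phone
    cur_syl <<- cur_syl + 1L
    cur <<- 0L
    cur_stressed <<- FALSE
    cur_accent_phone <<- 0L
  }

  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == ".") {
      close_syllable(i)
      explicit_boundary <- TRUE
    } else if (ch == "ˈ") {            # primary stress mark
      if (cur > 0L) {                       # mid-string mark implies a boundary
        close_syllable(i)
      }
      pending_stress <- TRUE
      n_stress_marks <- n_stress_marks + 1L
    } else if (ch == "ː") {            # length mark
      if (length(symbol) == 0L || cur == 0L) {
        stop("length mark with no preceding phone at position ", i,
             " in '", text, "'")
      }
      long[length(long)] <- TRUE
    } else if (ch %in% c("\u0300", "\u0301")) {  # grave/acute accent
      if (cur == 0L || category[length(category)] != "vowel") {
        stop("accent diacritic with no preceding vowel at position ", i,
             " in '", text, "'")
      }
      cur_stressed <- TRUE
      cur_accent_phone <- length(symbol)
      n_stress_marks <- n_stress_marks + 1L
    } else {
      rec <- get0(ch, envir = idx, inherits = FALSE)
      if (is.null(rec)) {
        stop("unknown symbol '", ch, "' at position ", i, " in '", text, "'")
      }
      symbol <- c(symbol, ch)
      category <- c(category, rec$category)
      long <- c(long, FALSE)
      syllable <- c(syllable, cur_syl)
      cur <- cur + 1L
      if (pending_stress) {
        # anchor stress to this phone so nucleus-based resyllabification can
        # keep it on the right syllable
        cur_stressed <- TRUE
        cur_accent_phone <- length(symbol)
        pending_stress <- FALSE
      }
    }
  }
  if (pending_stress) {
    stop("stress mark with no following syllable in '", text, "'")
  }
  close_syllable(length(chars) + 1L)

  if (n_stress_marks > 1L) {
    stop("more than one primary stress mark in '", text, "'")
  }

  n_syl <- cur_syl - 1L
  stressed_syl <- if (any(syl_stressed)) which(syl_stressed)[1] else NA_integer_
  v <- list(
    raw = text,
    subject_id = subject_id,
    symbol = symbol,
    base = symbol,
    category = category,
    long = long,
    syllable = syllable,
    stressed = stressed_syl,
    n_syllables = n_syl
  )
  # phone index of an accent diacritic, used if resyllabification is needed
  attr(v, "accent_phone") <-
    if (!is.na(stressed_syl) && stress_phone[stressed_syl] > 0L) {
      stress_phone[stressed_syl]
    } else {
      0L
    }
  class(v) <- "vocalization"

  if (!explicit_boundary) {
    v <- resyllabify(v)
  }
  v
}

normalize_char <- function(ch) {
  if (ch == "'" || ch == "’") return("ˈ")
  if (ch == ":") return("ː")
  pre <- precomposed_accents[[ch]]
  if (!is.null(pre)) return(pre)
  ch
}

# precomposed accented vowels decompose to base vowel + combining accent
precomposed_accents <- local({
  graves <- c("à" = "a", "è" = "e", "ì" = "i", "ò" = "o",
              "ù" = "u", "ỳ" = "y")
  acutes <- c("á" = "a", "é" = "e", "í" = "i", "ó" = "o",
              "ú" = "u", "ý" = "y")
  out <- c(lapply(graves, function(b) c(b, "\u0300")),
           lapply(acutes, function(b) c(b, "\u0301")))
  out
})

# Syllabify an unmarked vocalization by vowel nuclei with onset maximization.
resyllabify <- function(v) {
  nucleus <- v$category %in% c("vowel", "unknown-vowel")
  if (sum(nucleus) <= 1L) return(v)
  nuc_idx <- which(nucleus)
  syl <- integer(length(v$symbol))
  # phones up to and including the first nucleus: syllable 1; thereafter a new
  # syllable starts right after each nucleus (all intervocalic material joins
  # the following onset); trailing phones stay in the last syllable
  boundaries <- nuc_idx[-length(nuc_idx)]   # last phone index of each syllable
  s <- 1L
  prev <- 0L
  for (b in boundaries) {
    syl[(prev + 1L):b] <- s
    prev <- b
    s <- s + 1L
  }
  syl[(prev + 1L):length(syl)] <- s
  v$syllable <- syl
  v$n_syllables <- s
  # a stress mark on the original single syllable pins stress to the syllable
  # containing the accented vowel, or to the first syllable for a leading mark
  if (!is.na(v$stressed)) {
    ap <- attr(v, "accent_phone")
    v$stressed <- if (!is.null(ap) && ap > 0L) syl[ap] else 1L
  }
  v
}

#' @export
format.vocalization <- function(x, ...) {
  sym <- ifelse(x$long, paste0(x$symbol, "ː"), x$symbol)
  syls <- vapply(seq_len(x$n_syllables), function(s) {
    paste0(sym[x$syllable == s], collapse = "")
  }, character(1))
  if (!is.na(x$stressed)) {
    syls[x$stressed] <- paste0("ˈ", syls[x$stressed])
  }
  paste0(syls, collapse = ".")
}

#' @export
print.vocalization <- function(x, ...) {
  cat("<vocalization> ", format(x), "  (", x$n_syllables, " syllable",
      if (x$n_syllables != 1) "s", ")\n", sep = "")
  invisible(x)
}

#' @export
as.character.vocalization <- function(x, ...) format(x)

#' Phone-level view of a vocalization
#'
#' @param v A `vocalization` from [parse_transcription()].
#' @param inventory Inventory used to attach sound classes.
#' @return A tibble with one row per phone: syllable index, symbol (length
#'   mark included), category, length flag and the list-column `classes`.
#' @export
phones <- function(v, inventory = default_inventory()) {
  stopifnot(inherits(v, "vocalization"))
  idx <- inventory_index(inventory)
  classes <- lapply(seq_along(v$symbol), function(i) {
    phone_classes(v$symbol[i], v$long[i], idx)
  })
  tibble::tibble(
    syllable = v$syllable,
    symbol = ifelse(v$long, paste0(v$symbol, "ː"), v$symbol),
    category = v$category,
    long = v$long,
    classes = classes
  )
}

phone_classes <- function(base, long, idx) {
  rec <- get0(base, envir = idx, inherits = FALSE)
  if (is.null(rec)) stop("unknown symbol '", base, "'")
  if (long) c(rec$classes, rec$classes_when_long) else rec$classes
}

#' Classify a single phone symbol
#'
#' @param symbol A phone symbol, optionally carrying a length mark
#'   (IPA length sign, ASCII ":" accepted).
#' @param inventory A [phone_inventory()].
#' @return A `phone` object: canonical `symbol`, `base`, `category`,
#'   `long`, and the character vector `classes` of complexity sound
#'   classes. Cover symbols (`C`, `V`, indeterminate) always have empty
#'   classes.
#' @examples
#' classify_phone("v")$classes
#' @export
classify_phone <- function(symbol, inventory = default_inventory()) {
  if (!is.character(symbol) || length(symbol) != 1 || !nzchar(symbol)) {
    stop("`symbol` must be a single non-empty string")
  }
  s <- gsub(":", "ː", symbol, fixed = TRUE)
  long <- grepl("ː$", s)
  base <- sub("ː$", "", s)
  idx <- inventory_index(inventory)
  rec <- get0(base, envir = idx, inherits = FALSE)
  if (is.null(rec)) stop("unknown symbol '", symbol, "'")
  out <- list(
    symbol = if (long) paste0(base, "ː") else base,
    base = base,
    category = rec$category,
    long = long,
    classes = phone_classes(base, long, idx)
  )
  class(out) <- "phone"
  out
}

#' @export
print.phone <- function(x, ...) {
  cat("<phone> ", x$symbol, ": ", x$category,
      if (length(x$classes) > 0) paste0(" {", paste(x$classes, collapse = ", "), "}"),
      "\n", sep = "")
  invisible(x)
}

#' Number of syllables in a parsed vocalization
#'
#' Equals the number of marked syllables; for input without boundary marks
#' it equals the number of vowel nuclei (see [parse_transcription()]).
#'
#' @param v A `vocalization`.
#' @return Integer syllable count.
#' @export
count_syllables <- function(v) {
  stopifnot(inherits(v, "vocalization"))
  v$n_syllables
}

#' Inter-transcriber character agreement
#'
#' Percentage of matching characters between two transcriptions of the same
#' vocalization under an optimal global alignment (matches are identical
#' characters; the optimal alignment maximizes them, i.e. the longest common
#' subsequence), relative to the longer string. Symmetric; 100 iff the
#' strings are identical.
#'
#' @param a,b Transcription strings.
#' @return Agreement percentage in \[0, 100\].
#' @examples
#' transcription_agreement("mama", "baba")  # 50
#' @export
transcription_agreement <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1 ||
      is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) {
    stop("both transcriptions must be single non-empty strings")
  }
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  # classic LCS dynamic program, row-rolled
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    match_i <- x[i] == y
    for (j in seq_len(m)) {
      cur[j + 1L] <- if (match_i[j]) prev[j] + 1L else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  100 * prev[m + 1L] / max(n, m)
}
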
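# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: character/regex recounts, generic geometry, and
# base-R alignment.

# generic polygon shoelace area (any number of vertices, in order)
oracle_shoelace <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# matched characters under optimal alignment via edit distance with
# substitution forbidden (cost 2 = delete + insert): LCS = (n + m - d) / 2
oracle_agreement <- function(a, b) {
  d <- utils::adist(a, b, costs = list(ins = 1, del = 1, sub = 2))[1, 1]
  n <- nchar(a); m <- nchar(b)
  100 * ((n + m - d) / 2) / max(n, m)
}

# flat regex/character recount of the WCM-SE score from a canonical
# transcription string (syllables dotted, stress as U+02C8, length as U+02D0)
oracle_wcm_flat <- function(s) {
  syls <- strsplit(gsub("ˈ", "", s), ".", fixed = TRUE)[[1]]
  poly <- as.integer(length(syls) > 2)
  stress_syl <- which(startsWith(strsplit(s, ".", fixed = TRUE)[[1]], "ˈ"))
  noninit <- as.integer(length(stress_syl) == 1 && stress_syl > 1)

  chars <- strsplit(gsub("[.ˈ]", "", s), "")[[1]]
  cons <- c("p","b","t","d","ʈ","ɖ","k","g","m","n","ɳ","ŋ","r","ʀ","ɾ",
            "f","v","s","ʂ","ʐ","ɕ","ʝ","ɧ","ʁ","h","ɹ","l","ɭ","j","C")
  vows <- c("i","y","ʉ","u","ɪ","ʏ","ʊ","e","ø","ɵ","o","ə","ɛ","œ","ɔ",
            "æ","a","ɑ","V")
  # word-final consonant: last character that is not a length mark
  core <- chars[chars != "ː"]
  final <- as.integer(core[length(core)] %in% cons)
  # clusters: maximal runs of >= 2 consonants; the indeterminate square and
  # vowels break runs; length marks are transparent (they attach to vowels)
  cls <- ifelse(chars %in% cons, "C", ifelse(chars %in% vows, "V", "B"))
  cls <- cls[chars != "ː"]
  runs <- gregexpr("CC+", paste(cls, collapse = ""))[[1]]
  n_clusters <- if (runs[1] == -1) 0L else length(runs)

  count <- function(set) sum(chars %in% set)
  velar <- count(c("k", "g", "ŋ", "ɧ"))
  liquid <- count(c("l", "ɭ", "ɹ"))
  fric <- count(c("f","v","s","ʐ","ʁ","ʂ","ʝ","h","ɧ","ɕ"))
  vfric <- count(c("v","ʐ","ʁ","ʝ"))
  trill <- count(c("r", "ʀ"))
  lfrv <- length(gregexpr("(y|ø|ʉ)ː", s)[[1]][gregexpr("(y|ø|ʉ)ː", s)[[1]] > 0])

  poly + noninit + final + n_clusters + velar + liquid + fric + vfric +
    3 * trill + lfrv
}

# random parseable transcription built from the packaged inventory
random_transcription <- function() {
  cons <- c("p","b","t","d","k","g","m","n","ŋ","r","f","v","s","h","l","ɧ",
            "ʀ","ɹ","C")
  vows <- c("a","e","i","o","u","y","ø","ʉ","ɛ","ɑ","V")
  n_syl <- sample(1:4, 1)
  syls <- vapply(seq_len(n_syl), function(s) {
    onset <- paste(sample(cons, sample(0:2, 1), replace = TRUE), collapse = "")
    nuc <- sample(vows, 1)
    if (stats::runif(1) < 0.25) nuc <- paste0(nuc, "ː")
    coda <- if (stats::runif(1) < 0.3) sample(cons, 1) else ""
    paste0(onset, nuc, coda)
  }, character(1))
  if (stats::runif(1) < 0.5) {
    k <- sample(n_syl, 1)
    syls[k] <- paste0("ˈ", syls[k])
  }
  paste(syls, collapse = ".")
}
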
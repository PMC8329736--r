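#' Phone inventory for transcription parsing and complexity scoring
#'
#' The inventory maps each transcription symbol to its broad category
#' (consonant, vowel, unknown-consonant, unknown-vowel, indeterminate) and to
#' the complexity sound classes it belongs to (velar, liquid, fricative,
#' voiced-fricative, trill, long-front-rounded-vowel). Class membership is
#' independent and possibly multiple: a voiced fricative is also a fricative,
#' and the dorsal fricative is both velar and fricative.
#'
#' Classes in the `classes_when_long` column apply only when the symbol
#' carries a length mark ("ː"): the long-front-rounded-vowel class
#' requires phonological length. The packaged default covers the Swedish
#' consonant and vowel inventories used for transcribing infant
#' vocalizations, plus the cover symbols `C` (consonant-like), `V`
#' (vowel-like) and the indeterminate square.
#'
#' @param path Path to a tab-separated inventory file with columns `symbol`,
#'   `category`, `classes`, `classes_when_long`, `notes`. Defaults to the
#'   inventory shipped with the package.
#' @return A `phone_inventory` object: a tibble with one row per symbol and
#'   list-columns of sound classes.
#' @examples
#' inv <- phone_inventory()
#' subset(inv, symbol == "v")
#' @export
phone_inventory <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "phone_inventory.tsv", package = "phonadapt")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("inventory file not found: ", path)
  }
  raw <- utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                           encoding = "UTF-8", na.strings = character())
  required <- c("symbol", "category", "classes", "classes_when_long")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("inventory file lacks columns: ", paste(missing, collapse = ", "))
  }
  inv <- tibble::tibble(
    symbol = raw$symbol,
    category = raw$category,
    classes = split_classes(raw$classes),
    classes_when_long = split_classes(raw$classes_when_long),
    notes = if ("notes" %in% names(raw)) raw$notes else ""
  )
  validate_inventory(inv)
}

split_classes <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character() else trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  })
}

valid_categories <- c("consonant", "vowel", "unknown-consonant", "unknown-vowel",
                      "indeterminate")
consonant_classes <- c("velar", "liquid", "fricative", "voiced-fricative", "trill")
vowel_classes <- c("long-front-rounded-vowel")

validate_inventory <- function(inv) {
  if (anyDuplicated(inv$symbol)) {
    dup <- inv$symbol[duplicated(inv$symbol)]
    stop("inventory maps symbol(s) to conflicting entries: ",
         paste(unique(dup), collapse = ", "))
  }
  bad_cat <- setdiff(unique(inv$category), valid_categories)
  if (length(bad_cat) > 0) {
    stop("unknown inventory categories: ", paste(bad_cat, collapse = ", "))
  }
  all_classes <- c(consonant_classes, vowel_classes)
  for (i in seq_len(nrow(inv))) {
    cls <- union(inv$classes[[i]], inv$classes_when_long[[i]])
    bad <- setdiff(cls, all_classes)
    if (length(bad) > 0) {
      stop("symbol '", inv$symbol[i], "' has unknown classes: ",
           paste(bad, collapse = ", "))
    }
    cat_i <- inv$category[i]
    if (cat_i %in% c("unknown-consonant", "unknown-vowel", "indeterminate") &&
        length(cls) > 0) {
      stop("symbol '", inv$symbol[i], "': cover symbols may not carry classes")
    }
    if (cat_i == "vowel" && length(intersect(cls, consonant_classes)) > 0) {
      stop("symbol '", inv$symbol[i], "': consonant classes on a vowel")
    }
    if (cat_i == "consonant" && length(intersect(cls, vowel_classes)) > 0) {
      stop("symbol '", inv$symbol[i], "': vowel classes on a consonant")
    }
  }
  class(inv) <- c("phone_inventory", class(inv))
  inv
}

# Fast lookup environment keyed by symbol; built once per inventory object.
inventory_index <- function(inventory) {
  idx <- attr(inventory, "index")
  if (!is.null(idx)) return(idx)
  idx <- new.env(parent = emptyenv(), size = nrow(inventory) * 2L)
  for (i in seq_len(nrow(inventory))) {
    assign(inventory$symbol[i],
           list(category = inventory$category[i],
                classes = inventory$classes[[i]],
                classes_when_long = inventory$classes_when_long[[i]]),
           envir = idx)
  }
  idx
}

the_default_inventory <- new.env(parent = emptyenv())

default_inventory <- function() {
  if (is.null(the_default_inventory$inv)) {
    inv <- phone_inventory()
    attr(inv, "index") <- inventory_index(inv)
    the_default_inventory$inv <- inv
  }
  the_default_inventory$inv
}
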
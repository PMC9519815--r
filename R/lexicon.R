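#' Phoneme inventory
#'
#' An inventory maps phoneme symbols (possibly multi-character, e.g. the
#' affricate \code{"d͡ʒ"}) to their segmental class. Because phoneme
#' strings are always space-delimited in this package, multi-character IPA
#' symbols are unambiguous: each whitespace-separated unit is matched exactly
#' against the inventory.
#'
#' @param symbols character vector of phoneme symbols.
#' @param classes character vector of the same length; each element is
#'   \code{"consonant"} or \code{"vowel"}.
#' @return An object of class \code{phoneme_inventory}: a data.frame with
#'   columns \code{symbol} and \code{class}.
#' @examples
#' inv <- phoneme_inventory(c("b", "a", "t"), c("consonant", "vowel", "consonant"))
#' tokenize_phonemes("b a t a", inv)
#' @export
phoneme_inventory <- function(symbols, classes) {
  symbols <- as.character(symbols)
  classes <- as.character(classes)
  if (length(symbols) == 0L) stop("inventory must contain at least one symbol")
  if (length(symbols) != length(classes)) {
    stop("`symbols` and `classes` must have the same length")
  }
  if (anyDuplicated(symbols)) {
    stop("duplicated inventory symbols: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  }
  if (any(!nzchar(symbols))) stop("inventory symbols must be non-empty")
  bad <- !classes %in% c("consonant", "vowel")
  if (any(bad)) {
    stop("unknown phoneme class: ", paste(unique(classes[bad]), collapse = ", "))
  }
  structure(data.frame(symbol = symbols, class = classes,
                       stringsAsFactors = FALSE),
            class = c("phoneme_inventory", "data.frame"))
}

#' Read a phoneme inventory from a two-column TSV (symbol, class)
#'
#' @param path path to a UTF-8 tab-separated file with no header.
#' @return A \code{\link{phoneme_inventory}}.
#' @export
read_inventory <- function(path) {
  if (!file.exists(path)) stop("inventory file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#", fileEncoding = "UTF-8",
                           strip.white = TRUE)
  if (ncol(tab) < 2L) stop("inventory file must have two columns (symbol, class)")
  phoneme_inventory(tab[[1]], tab[[2]])
}

#' Classes of phonemes under an inventory
#' @param phonemes character vector of phoneme tokens.
#' @param inventory a \code{\link{phoneme_inventory}}.
#' @return character vector of \code{"consonant"}/\code{"vowel"}.
#' @export
phoneme_classes <- function(phonemes, inventory) {
  idx <- match(phonemes, inventory$symbol)
  if (anyNA(idx)) {
    stop("phoneme(s) not in inventory: ",
         paste(unique(phonemes[is.na(idx)]), collapse = ", "))
  }
  inventory$class[idx]
}

#' Tokenize a space-delimited phoneme string
#'
#' Splits \code{raw} on whitespace and matches every unit exactly against the
#' inventory. Tokenization is deterministic and total on valid input; unknown
#' symbols raise an error naming the symbol and its position.
#'
#' @param raw a whitespace-delimited phoneme string, e.g. \code{"t a d͡ʒ i"}.
#' @param inventory a \code{\link{phoneme_inventory}}.
#' @return character vector of phoneme tokens.
#' @export
tokenize_phonemes <- function(raw, inventory) {
  if (length(raw) != 1L || is.na(raw)) stop("`raw` must be a single string")
  toks <- strsplit(trimws(raw), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) stop("empty phoneme string")
  unknown <- which(!toks %in% inventory$symbol)
  if (length(unknown)) {
    stop(sprintf("unknown phoneme symbol '%s' at position %d",
                 toks[unknown[1]], unknown[1]))
  }
  toks
}

new_lexicon <- function(orthography, phonemes, frequency) {
  structure(data.frame(orthography = orthography,
                       phonemes = I(phonemes),
                       frequency = as.integer(frequency),
                       stringsAsFactors = FALSE),
            class = c("lexicon", "data.frame"))
}

#' Read a phonemic frequency lexicon
#'
#' Reads a UTF-8 tab-separated file with three columns per row: orthography,
#' space-delimited phoneme string, integer token frequency (>= 1). Rows that
#' fail validation (wrong arity, non-integer or non-positive frequency, a
#' phoneme outside the inventory, empty phoneme string) are skipped with a
#' warning that reports their line numbers, or abort the read in strict mode.
#'
#' @param path path to the lexicon TSV.
#' @param inventory a \code{\link{phoneme_inventory}}.
#' @param strict if \code{TRUE}, any invalid row is an error; otherwise
#'   invalid rows are dropped with a warning listing line numbers.
#' @return An object of class \code{lexicon}: a data.frame with columns
#'   \code{orthography}, \code{phonemes} (list of token vectors) and
#'   \code{frequency}.
#' @export
read_lexicon <- function(path, inventory, strict = FALSE) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  line_no <- which(keep)
  lines <- lines[keep]
  orth <- character(0); phon <- list(); freq <- integer(0)
  bad <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    msg <- NULL
    if (length(fields) != 3L) {
      msg <- sprintf("line %d: expected 3 tab-separated fields, got %d",
                     line_no[i], length(fields))
    } else {
      f <- suppressWarnings(as.numeric(trimws(fields[3])))
      toks <- tryCatch(tokenize_phonemes(fields[2], inventory),
                       error = function(e) {
                         structure(conditionMessage(e), class = "tok_error")
                       })
      if (inherits(toks, "tok_error")) {
        msg <- sprintf("line %d: %s", line_no[i], unclass(toks))
      } else if (is.na(f) || f != round(f) || f < 1) {
        msg <- sprintf("line %d: frequency must be an integer >= 1 (got '%s')",
                       line_no[i], trimws(fields[3]))
      } else {
        orth <- c(orth, trimws(fields[1]))
        phon <- c(phon, list(toks))
        freq <- c(freq, as.integer(f))
      }
    }
    if (!is.null(msg)) {
      if (strict) stop(msg)
      bad <- c(bad, msg)
    }
  }
  if (length(bad)) {
    warning(sprintf("skipped %d invalid lexicon row(s):\n  %s",
                    length(bad), paste(bad, collapse = "\n  ")))
  }
  if (length(orth) == 0L) stop("no valid lexicon rows in ", path)
  new_lexicon(orth, phon, freq)
}

#' Write a lexicon back to its TSV form
#'
#' Inverse of \code{\link{read_lexicon}} up to delimiter normalization:
#' phonemes are rejoined with single spaces.
#'
#' @param lexicon a \code{lexicon}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  lines <- vapply(seq_len(nrow(lexicon)), function(i) {
    paste(lexicon$orthography[i],
          paste(lexicon$phonemes[[i]], collapse = " "),
          lexicon$frequency[i], sep = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a lexicon from vectors (one phoneme string per word)
#'
#' Convenience constructor used throughout the package and its tests.
#'
#' @param words named integer vector (names = space-delimited phoneme strings,
#'   values = token frequencies) or a data.frame with columns
#'   \code{orthography}, \code{phonemes}, \code{frequency}.
#' @param inventory a \code{\link{phoneme_inventory}}.
#' @export
as_lexicon <- function(words, inventory) {
  if (is.data.frame(words)) {
    phon <- lapply(words$phonemes, tokenize_phonemes, inventory = inventory)
    return(new_lexicon(words$orthography, phon, words$frequency))
  }
  phon <- lapply(names(words), tokenize_phonemes, inventory = inventory)
  orth <- vapply(phon, paste, character(1), collapse = "")
  new_lexicon(orth, phon, unname(words))
}

#' @export
print.phoneme_inventory <- function(x, ...) {
  cat(sprintf("<phoneme_inventory> %d symbols (%d consonants, %d vowels)\n",
              nrow(x), sum(x$class == "consonant"), sum(x$class == "vowel")))
  invisible(x)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %d entries, total token frequency %s\n",
              nrow(x), format(sum(x$frequency), big.mark = ",")))
  invisible(x)
}
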
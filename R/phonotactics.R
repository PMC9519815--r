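#' Positional biphone phonotactic probability table
#'
#' Computes log-weighted positional biphone probabilities from a frequency
#' lexicon. For every position \eqn{p} (1-based index of the biphone's first
#' segment) and ordered phoneme pair \eqn{b}:
#' \deqn{prob(p, b) = \frac{\sum_{w : b \; at \; p} \log_{10} freq(w)}
#'                          {\sum_{w : any \; biphone \; at \; p} \log_{10} freq(w)}}
#' i.e. the summed log10 token frequency of words carrying that biphone at
#' that position, divided by the total log10 token frequency of all words
#' having any biphone at that position (words of length >= p + 1).
#'
#' No smoothing is applied: \code{log10(1) = 0}, so words of token frequency 1
#' legally contribute zero weight. Positions whose denominator is zero carry
#' no entries. Within each position with a positive denominator the
#' probabilities sum to 1.
#'
#' @param lexicon a \code{lexicon} (see \code{\link{read_lexicon}}).
#' @return An object of class \code{biphone_table}: a list with
#'   \describe{
#'     \item{prob}{data.frame \code{position, ph1, ph2, numerator,
#'       denominator, probability}, one row per observed positional biphone}
#'     \item{denom}{named numeric vector, total log10 token frequency per
#'       position}
#'     \item{source_size}{number of lexicon entries used}
#'   }
#' @export
biphone_table <- function(lexicon) {
  if (!nrow(lexicon)) stop("empty lexicon")
  logf <- log10(as.numeric(lexicon$frequency))
  pos <- integer(0); p1 <- character(0); p2 <- character(0); w <- numeric(0)
  max_pos <- 0L
  for (i in seq_len(nrow(lexicon))) {
    ph <- lexicon$phonemes[[i]]
    n <- length(ph)
    if (n < 2L) next
    max_pos <- max(max_pos, n - 1L)
    idx <- seq_len(n - 1L)
    pos <- c(pos, idx)
    p1 <- c(p1, ph[idx])
    p2 <- c(p2, ph[idx + 1L])
    w <- c(w, rep(logf[i], n - 1L))
  }
  if (!length(pos)) stop("no biphones anywhere: all lexicon words have length 1")
  # denominator: words with >= 1 biphone at position p, i.e. length >= p + 1
  lens <- vapply(lexicon$phonemes, length, integer(1))
  denom <- vapply(seq_len(max_pos), function(p) sum(logf[lens >= p + 1L]),
                  numeric(1))
  names(denom) <- as.character(seq_len(max_pos))
  key <- paste(pos, p1, p2, sep = "\r")
  num <- tapply(w, key, sum)
  parts <- strsplit(names(num), "\r", fixed = TRUE)
  tab <- data.frame(
    position = as.integer(vapply(parts, `[[`, character(1), 1L)),
    ph1 = vapply(parts, `[[`, character(1), 2L),
    ph2 = vapply(parts, `[[`, character(1), 3L),
    numerator = as.numeric(num),
    stringsAsFactors = FALSE
  )
  tab$denominator <- denom[as.character(tab$position)]
  tab <- tab[tab$denominator > 0, , drop = FALSE]
  tab$probability <- tab$numerator / tab$denominator
  tab <- tab[order(tab$position, tab$ph1, tab$ph2), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(prob = tab, denom = denom, source_size = nrow(lexicon)),
            class = "biphone_table")
}

#' Look up positional biphone probabilities
#'
#' @param table a \code{\link{biphone_table}}.
#' @param position integer vector (1-based first-segment index).
#' @param ph1,ph2 character vectors, first and second phoneme of the biphone.
#' @return numeric vector of probabilities; unseen pairs return 0.
#' @export
biphone_prob <- function(table, position, ph1, ph2) {
  key <- paste(position, ph1, ph2, sep = "\r")
  tk <- paste(table$prob$position, table$prob$ph1, table$prob$ph2, sep = "\r")
  p <- table$prob$probability[match(key, tk)]
  p[is.na(p)] <- 0
  p
}

#' Score a word's phonotactic probability
#'
#' Decomposes the word into positional biphones, looks each up in the table
#' (unseen pairs contribute probability 0 and are flagged), and aggregates to
#' a single word-level phonotactic probability (PP). The default aggregation
#' is the sum of biphone probabilities (the positional-statistic convention);
#' the mean is available as an option.
#'
#' @param phonemes character vector of phoneme tokens, length >= 2.
#' @param table a \code{\link{biphone_table}}.
#' @param aggregation \code{"sum"} (default) or \code{"mean"}.
#' @return An object of class \code{scored_word}: list with \code{phonemes},
#'   \code{biphone_probs} (data.frame \code{position, ph1, ph2, probability,
#'   seen}), \code{pp}, \code{aggregation}, \code{all_unseen}.
#' @export
score_word <- function(phonemes, table, aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  n <- length(phonemes)
  if (n < 2L) stop("cannot score a word shorter than 2 phonemes")
  idx <- seq_len(n - 1L)
  probs <- biphone_prob(table, idx, phonemes[idx], phonemes[idx + 1L])
  bp <- data.frame(position = idx, ph1 = phonemes[idx], ph2 = phonemes[idx + 1L],
                   probability = probs, seen = probs > 0,
                   stringsAsFactors = FALSE)
  pp <- if (aggregation == "sum") sum(probs) else mean(probs)
  structure(list(phonemes = phonemes, biphone_probs = bp, pp = pp,
                 aggregation = aggregation, all_unseen = all(!bp$seen)),
            class = "scored_word")
}

#' Mean phonotactic probability of a set of words
#'
#' @param words a list of \code{scored_word} objects, a \code{stimulus_set},
#'   or a numeric vector of per-word PP values.
#' @return the arithmetic mean PP.
#' @export
set_mean_pp <- function(words) {
  if (inherits(words, "stimulus_set")) words <- words$words
  if (is.numeric(words)) {
    if (!length(words)) stop("empty set")
    return(mean(words))
  }
  if (!length(words)) stop("empty set")
  mean(vapply(words, function(w) w$pp, numeric(1)))
}

#' Serialize / read a biphone table as TSV
#'
#' Columns: position, phoneme1, phoneme2, probability, numerator, denominator.
#' @param table a \code{\link{biphone_table}}.
#' @param path output (input) path.
#' @return \code{path} invisibly (\code{write_biphone_table});
#'   the table's \code{prob} data.frame (\code{read_biphone_table}).
#' @export
write_biphone_table <- function(table, path) {
  out <- table$prob[, c("position", "ph1", "ph2", "probability",
                        "numerator", "denominator")]
  names(out) <- c("position", "phoneme1", "phoneme2", "probability",
                  "numerator", "denominator")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_biphone_table
#' @export
read_biphone_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  names(tab)[names(tab) == "phoneme1"] <- "ph1"
  names(tab)[names(tab) == "phoneme2"] <- "ph2"
  denom <- tapply(tab$denominator, tab$position, `[`, 1L)
  structure(list(prob = tab, denom = denom, source_size = NA_integer_),
            class = "biphone_table")
}

#' @export
print.biphone_table <- function(x, ...) {
  cat(sprintf("<biphone_table> %d positional biphones over %d positions (from %s words)\n",
              nrow(x$prob), length(x$denom),
              ifelse(is.na(x$source_size), "?", x$source_size)))
  invisible(x)
}

#' @export
print.scored_word <- function(x, ...) {
  cat(sprintf("<scored_word> /%s/  pp = %.6f (%s of %d biphone probabilities)%s\n",
              paste(x$phonemes, collapse = " "), x$pp, x$aggregation,
              nrow(x$biphone_probs),
              if (x$all_unseen) "  [all biphones unseen]" else ""))
  invisible(x)
}
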
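#' Stimulus set of scored pseudowords
#'
#' @param words list of \code{scored_word} objects.
#' @param label \code{"PP_plus"} or \code{"PP_minus"}.
#' @param lexicon optional \code{lexicon}; when supplied, every word is
#'   checked to be novel (its phoneme sequence absent from the lexicon).
#' @return An object of class \code{stimulus_set}: list with \code{label},
#'   \code{words}, \code{mean_pp}.
#' @export
stimulus_set <- function(words, label = c("PP_plus", "PP_minus"),
                         lexicon = NULL) {
  label <- match.arg(label)
  if (!length(words)) stop("empty stimulus set")
  keys <- vapply(words, function(w) paste(w$phonemes, collapse = " "),
                 character(1))
  if (anyDuplicated(keys)) stop("stimulus set words must be mutually distinct")
  if (!is.null(lexicon)) {
    lex_keys <- vapply(lexicon$phonemes, paste, character(1), collapse = " ")
    hit <- keys %in% lex_keys
    if (any(hit)) {
      stop("stimulus set words must be novel; found in lexicon: ",
           paste(keys[hit], collapse = ", "))
    }
  }
  structure(list(label = label, words = words, mean_pp = set_mean_pp(words)),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %s: %d words, mean pp = %.6f\n",
              x$label, length(x$words), x$mean_pp))
  for (w in x$words) {
    cat(sprintf("  /%s/  %.6f\n", paste(w$phonemes, collapse = " "), w$pp))
  }
  invisible(x)
}

lexicon_keys <- function(lexicon) {
  vapply(lexicon$phonemes, paste, character(1), collapse = " ")
}

#' Enumerate and rank pseudoword candidates for a CV template
#'
#' The search engine: enumerates every phoneme sequence matching the
#' consonant/vowel template whose adjacent pairs chain through the biphone
#' table (the biphone at position p must be attested at position p and end
#' with the segment the biphone at p + 1 starts with), scores each candidate,
#' drops any sequence already present in the lexicon (novelty filter), and
#' returns the ranking sorted by descending PP with a lexicographic
#' tie-break on the phoneme sequence.
#'
#' @param table a \code{\link{biphone_table}}.
#' @param inventory a \code{\link{phoneme_inventory}}.
#' @param lexicon a \code{lexicon}; candidates equal to one of its phoneme
#'   sequences are excluded.
#' @param template character vector over \code{c("C", "V")}; default CVCV.
#' @param aggregation passed to \code{\link{score_word}}.
#' @return data.frame of class \code{candidate_ranking} with columns
#'   \code{word} (space-delimited phonemes) and \code{pp}, best first.
#' @export
generate_candidates <- function(table, inventory, lexicon,
                                template = c("C", "V", "C", "V"),
                                aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  if (length(template) < 2L) stop("template must have length >= 2")
  if (!all(template %in% c("C", "V"))) stop("template symbols must be C or V")
  cls <- c(C = "consonant", V = "vowel")[template]
  tab <- table$prob
  # chain positional biphones left to right
  seqs <- NULL
  for (p in seq_len(length(template) - 1L)) {
    bp <- tab[tab$position == p, , drop = FALSE]
    cls1 <- phoneme_classes(bp$ph1, inventory)
    cls2 <- phoneme_classes(bp$ph2, inventory)
    bp <- bp[cls1 == cls[p] & cls2 == cls[p + 1L], , drop = FALSE]
    if (!nrow(bp)) stop("biphone table has no entries matching the template at position ", p)
    if (is.null(seqs)) {
      seqs <- lapply(seq_len(nrow(bp)), function(i) c(bp$ph1[i], bp$ph2[i]))
    } else {
      ext <- list()
      for (s in seqs) {
        nxt <- bp$ph2[bp$ph1 == s[length(s)]]
        for (ph in nxt) ext[[length(ext) + 1L]] <- c(s, ph)
      }
      seqs <- ext
      if (!length(seqs)) stop("no chainable candidates for the template")
    }
  }
  keys <- vapply(seqs, paste, character(1), collapse = " ")
  novel <- !keys %in% lexicon_keys(lexicon)
  seqs <- seqs[novel]; keys <- keys[novel]
  if (!length(seqs)) stop("no chainable candidates for the template (all collide with the lexicon)")
  pp <- vapply(seqs, function(s) score_word(s, table, aggregation)$pp, numeric(1))
  ord <- order(-pp, keys)
  structure(data.frame(word = keys[ord], pp = pp[ord], stringsAsFactors = FALSE),
            class = c("candidate_ranking", "data.frame"),
            aggregation = aggregation)
}

word_biphone_keys <- function(phonemes) {
  idx <- seq_len(length(phonemes) - 1L)
  paste(idx, phonemes[idx], phonemes[idx + 1L], sep = "\r")
}

#' Select a maximal-PP stimulus set from a candidate ranking
#'
#' Greedy selection down the ranking, skipping candidates that violate the
#' diversity constraints against the already-chosen words:
#' \describe{
#'   \item{max_shared_biphones}{maximum number of positional biphones a
#'     candidate may share with any already-chosen word (\code{Inf} disables)}
#'   \item{max_initial_repeats}{maximum number of chosen words sharing the
#'     same initial phoneme (\code{Inf} disables)}
#' }
#' With constraints disabled the result is exactly the top-k by PP.
#'
#' @param candidates a \code{candidate_ranking}.
#' @param table the \code{\link{biphone_table}} used to score candidates.
#' @param k number of words (default 6).
#' @param constraints list with elements \code{max_shared_biphones},
#'   \code{max_initial_repeats}.
#' @param label set label for the result (default \code{"PP_plus"}).
#' @param lexicon optional lexicon for the novelty invariant check.
#' @return a \code{\link{stimulus_set}}.
#' @export
select_top_set <- function(candidates, table, k = 6,
                           constraints = list(max_shared_biphones = Inf,
                                              max_initial_repeats = Inf),
                           label = "PP_plus", lexicon = NULL) {
  if (nrow(candidates) < k) {
    stop(sprintf("need %d candidates, have %d", k, nrow(candidates)))
  }
  msb <- constraints$max_shared_biphones %||% Inf
  mir <- constraints$max_initial_repeats %||% Inf
  chosen <- list(); chosen_keys <- list(); initials <- character(0)
  for (i in seq_len(nrow(candidates))) {
    ph <- strsplit(candidates$word[i], " ", fixed = TRUE)[[1]]
    bk <- word_biphone_keys(ph)
    shared_ok <- all(vapply(chosen_keys,
                            function(x) sum(bk %in% x) <= msb, logical(1)))
    init_ok <- sum(initials == ph[1]) < mir
    if (shared_ok && init_ok) {
      chosen[[length(chosen) + 1L]] <- ph
      chosen_keys[[length(chosen_keys) + 1L]] <- bk
      initials <- c(initials, ph[1])
      if (length(chosen) == k) break
    }
  }
  if (length(chosen) < k) {
    stop(sprintf("only %d constraint-satisfying candidates (need %d)",
                 length(chosen), k))
  }
  words <- lapply(chosen, score_word, table = table,
                  aggregation = attr(candidates, "aggregation") %||% "sum")
  stimulus_set(words, label = label, lexicon = lexicon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recombine a PP+ set into a matched slightly-lower-PP set
#'
#' Reuses the material of the high-probability set in new arrangements and
#' selects six novel words whose set mean PP is strictly below the PP+ mean
#' but above a configurable floor (a fraction of the PP+ mean), i.e.
#' "slightly less probable, but still high".
#'
#' Two recombination modes:
#' \describe{
#'   \item{syllable}{(default) the CV syllables of the PP+ words are reused
#'     in new orders and positions (a word-final syllable may reappear
#'     word-initially, e.g. PP+ \emph{su-te}/\emph{vi-ko} yielding
#'     \emph{ko-su})}
#'   \item{biphone}{candidates are CV-template sequences built only from
#'     biphones occurring somewhere in the PP+ words}
#' }
#' Candidates are ranked by descending PP; the selection is the best
#' contiguous window of k candidates down the ranking whose mean satisfies
#' the ordering and floor constraints, which keeps the result deterministic.
#'
#' @param pp_plus a \code{\link{stimulus_set}} labelled \code{PP_plus}.
#' @param table the \code{\link{biphone_table}}.
#' @param inventory a \code{\link{phoneme_inventory}}.
#' @param lexicon the source \code{lexicon} (novelty filter).
#' @param k number of words (default 6).
#' @param floor lower bound on mean(PP-) as a fraction of mean(PP+); default 0.75.
#' @param mode \code{"syllable"} or \code{"biphone"}.
#' @return a \code{\link{stimulus_set}} labelled \code{PP_minus}.
#' @export
recombine_biphones <- function(pp_plus, table, inventory, lexicon, k = 6,
                               floor = 0.75, mode = c("syllable", "biphone")) {
  mode <- match.arg(mode)
  if (!inherits(pp_plus, "stimulus_set") || pp_plus$label != "PP_plus") {
    stop("`pp_plus` must be a stimulus_set labelled PP_plus")
  }
  agg <- pp_plus$words[[1]]$aggregation
  plus_keys <- vapply(pp_plus$words, function(w) paste(w$phonemes, collapse = " "),
                      character(1))
  if (mode == "syllable") {
    syll <- unique(unlist(lapply(pp_plus$words, function(w) {
      ph <- w$phonemes
      if (length(ph) %% 2L != 0L) stop("syllable recombination needs CV syllable words (even length)")
      vapply(seq_len(length(ph) / 2L),
             function(s) paste(ph[c(2L * s - 1L, 2L * s)], collapse = " "),
             character(1))
    }), use.names = FALSE))
    cand <- as.vector(outer(syll, syll, paste))
  } else {
    bps <- unique(unlist(lapply(pp_plus$words, function(w) {
      ph <- w$phonemes
      idx <- seq_len(length(ph) - 1L)
      paste(ph[idx], ph[idx + 1L])
    }), use.names = FALSE))
    parts <- strsplit(bps, " ", fixed = TRUE)
    len <- length(pp_plus$words[[1]]$phonemes)
    seqs <- lapply(parts, identity)
    for (p in seq_len(len - 2L)) {
      ext <- list()
      for (s in seqs) {
        nxt <- vapply(parts, function(b) b[1] == s[length(s)], logical(1))
        for (b in parts[nxt]) ext[[length(ext) + 1L]] <- c(s, b[2])
      }
      seqs <- ext
    }
    cand <- vapply(seqs, paste, character(1), collapse = " ")
  }
  cand <- setdiff(unique(cand), c(plus_keys, lexicon_keys(lexicon)))
  if (length(cand) < k) stop("recombination space exhausted before ", k, " feasible words")
  pp <- vapply(strsplit(cand, " ", fixed = TRUE),
               function(s) score_word(s, table, agg)$pp, numeric(1))
  ord <- order(-pp, cand)
  cand <- cand[ord]; pp <- pp[ord]
  target <- pp_plus$mean_pp
  sel <- NULL
  for (i in seq_len(length(cand) - k + 1L)) {
    m <- mean(pp[i:(i + k - 1L)])
    if (m < target && m >= floor * target) { sel <- i:(i + k - 1L); break }
    if (m < floor * target) break
  }
  if (is.null(sel)) {
    stop("recombination cannot produce a set with mean pp strictly below ",
         sprintf("%.6f and above %.2f of it", target, floor))
  }
  words <- lapply(strsplit(cand[sel], " ", fixed = TRUE), score_word,
                  table = table, aggregation = agg)
  stimulus_set(words, label = "PP_minus", lexicon = lexicon)
}
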
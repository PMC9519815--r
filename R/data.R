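#' Published stimulus words and their phonotactic probabilities
#'
#' The twelve CVCV pseudowords of the two stimulus sets with their printed
#' per-word phonotactic probabilities (six high-probability PP+ items and
#' six slightly lower PP- items built by recombining their syllables).
#' These printed values are inputs: the original biphone corpus is not
#' required to reproduce the set-level means (0.0085 and 0.0073).
#'
#' @return data.frame \code{set_label, orthography, phonemes, pp}.
#' @examples
#' st <- study_stimuli()
#' set_mean_pp(st$pp[st$set_label == "PP_plus"])
#' @export
study_stimuli <- function() {
  path <- system.file("extdata", "study_word_pp.tsv", package = "cswltools",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Bundled synthetic toy lexicon and phoneme inventory
#'
#' A small invented Brazilian-Portuguese-flavoured frequency lexicon (and
#' its phoneme inventory) for demonstrations, tests and the one-shot
#' pipeline. Orthographies and token frequencies are synthetic.
#'
#' @return \code{toy_inventory()}: a \code{\link{phoneme_inventory}};
#'   \code{toy_lexicon()}: a \code{lexicon}.
#' @export
toy_inventory <- function() {
  read_inventory(system.file("extdata", "inventory_bp.tsv",
                             package = "cswltools", mustWork = TRUE))
}

#' @rdname toy_inventory
#' @export
toy_lexicon <- function() {
  read_lexicon(system.file("extdata", "toy_lexicon_synthetic.tsv",
                           package = "cswltools", mustWork = TRUE),
               toy_inventory())
}
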
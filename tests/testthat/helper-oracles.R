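# Independent brute-force oracle for positional biphone probabilities:
# plain nested loops over words x positions, no shared code with the
# implementation's tapply-based aggregation.
oracle_biphone_table <- function(lexicon) {
  out <- list()
  max_len <- max(vapply(lexicon$phonemes, length, integer(1)))
  for (p in seq_len(max_len - 1L)) {
    denom <- 0
    for (i in seq_len(nrow(lexicon))) {
      if (length(lexicon$phonemes[[i]]) >= p + 1L) {
        denom <- denom + log10(lexicon$frequency[i])
      }
    }
    if (denom <= 0) next
    nums <- list()
    for (i in seq_len(nrow(lexicon))) {
      ph <- lexicon$phonemes[[i]]
      if (length(ph) >= p + 1L) {
        key <- paste(ph[p], ph[p + 1L])
        nums[[key]] <- (nums[[key]] %||% 0) + log10(lexicon$frequency[i])
      }
    }
    for (key in names(nums)) {
      out[[paste(p, key)]] <- nums[[key]] / denom
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# oracle word score: direct lookup in the oracle table
oracle_score <- function(phonemes, oracle, aggregation = "sum") {
  probs <- vapply(seq_len(length(phonemes) - 1L), function(p) {
    oracle[[paste(p, phonemes[p], phonemes[p + 1L])]] %||% 0
  }, numeric(1))
  if (aggregation == "sum") sum(probs) else mean(probs)
}

tiny_inventory <- function() {
  phoneme_inventory(c("b", "t", "k", "m", "n", "d", "a", "o", "i", "u"),
                    c(rep("consonant", 6), rep("vowel", 4)))
}

# seeded random lexicon over the tiny inventory (words of length 2-5)
random_lexicon <- function(seed, n_words = 12) {
  set.seed(seed)
  inv <- tiny_inventory()
  cons <- inv$symbol[inv$class == "consonant"]
  vows <- inv$symbol[inv$class == "vowel"]
  phon <- lapply(seq_len(n_words), function(i) {
    len <- sample(2:5, 1)
    vapply(seq_len(len), function(j) {
      if (j %% 2 == 1) sample(cons, 1) else sample(vows, 1)
    }, character(1))
  })
  new_lex <- data.frame(orthography = sprintf("w%02d", seq_len(n_words)),
                        phonemes = vapply(phon, paste, character(1),
                                          collapse = " "),
                        frequency = sample(1:5000, n_words, replace = TRUE))
  as_lexicon(new_lex, inv)
}

# small lexicon used across phonotactics/pseudoword tests
demo_lexicon <- function() {
  inv <- tiny_inventory()
  as_lexicon(c("b a t a" = 100L, "t a b o" = 10L, "b a b o" = 10L,
               "k o t a" = 500L, "m i n a" = 40L, "t a t u" = 30L,
               "n o t a" = 200L, "k a m a" = 60L, "b o k a" = 350L,
               "m a t o" = 25L), inv)
}

expect_no_violations <- function(design) {
  expect_identical(validate_design(design)$violations, character(0))
}
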
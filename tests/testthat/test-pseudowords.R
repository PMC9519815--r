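test_that("a one-consonant/one-vowel alphabet forces the single CVCV candidate", {
  inv <- phoneme_inventory(c("b", "a"), c("consonant", "vowel"))
  lex <- as_lexicon(c("b a b a b" = 10L), inv)
  tab <- biphone_table(lex)
  cand <- generate_candidates(tab, inv, lex)
  expect_identical(cand$word, "b a b a")
})

test_that("candidates equal to real lexicon words are excluded", {
  inv <- tiny_inventory()
  lex <- demo_lexicon()   # contains the CVCV words b a t a, k o t a, ...
  cand <- generate_candidates(biphone_table(lex), inv, lex)
  lex_keys <- vapply(lex$phonemes, paste, character(1), collapse = " ")
  expect_false(any(cand$word %in% lex_keys))
  expect_gt(nrow(cand), 0)
})

test_that("ranking matches exhaustive enumeration and scoring on a 2C/2V alphabet", {
  inv <- phoneme_inventory(c("b", "t", "a", "o"),
                           c("consonant", "consonant", "vowel", "vowel"))
  lex <- as_lexicon(c("b a t a" = 100L, "t o b o" = 40L, "b o t a" = 7L,
                      "t a b a" = 19L), inv)
  tab <- biphone_table(lex)
  cand <- generate_candidates(tab, inv, lex)
  # oracle: score all 16 CVCV strings by brute force, keep chainable + novel
  oracle <- oracle_biphone_table(lex)
  grid <- expand.grid(c1 = c("b", "t"), v1 = c("a", "o"), c2 = c("b", "t"),
                      v2 = c("a", "o"), stringsAsFactors = FALSE)
  words <- apply(grid, 1, function(r) paste(r, collapse = " "))
  chainable <- vapply(words, function(w) {
    ph <- strsplit(w, " ")[[1]]
    all(vapply(1:3, function(p) {
      !is.null(oracle[[paste(p, ph[p], ph[p + 1])]])
    }, logical(1)))
  }, logical(1))
  lex_keys <- vapply(lex$phonemes, paste, character(1), collapse = " ")
  keep <- chainable & !words %in% lex_keys
  pp <- vapply(words[keep], function(w) {
    oracle_score(strsplit(w, " ")[[1]], oracle)
  }, numeric(1))
  expected <- data.frame(word = words[keep], pp = unname(pp),
                         stringsAsFactors = FALSE)
  expected <- expected[order(-expected$pp, expected$word), ]
  rownames(expected) <- NULL
  expect_equal(cand$word, expected$word)
  expect_equal(cand$pp, expected$pp, tolerance = 1e-12)
})

test_that("top-set selection is top-k when unconstrained and honors constraints", {
  inv <- tiny_inventory()
  lex <- demo_lexicon()
  tab <- biphone_table(lex)
  cand <- generate_candidates(tab, inv, lex)
  top3 <- select_top_set(cand, tab, k = 3, lexicon = lex)
  expect_identical(vapply(top3$words, function(w) paste(w$phonemes, collapse = " "),
                          character(1)), cand$word[1:3])
  expect_s3_class(top3, "stimulus_set")
  expect_equal(top3$mean_pp, mean(cand$pp[1:3]))
  expect_error(select_top_set(cand, tab, k = nrow(cand) + 1), "candidates")
  # with no shared positional biphones allowed, greedy equals the exhaustive
  # best feasible set on this pool
  k <- 3
  pool <- utils::head(cand, 30)
  strict <- select_top_set(pool, tab, k = k,
                           constraints = list(max_shared_biphones = 0))
  shares <- function(w1, w2) {
    b <- function(w) {
      ph <- strsplit(w, " ")[[1]]
      paste(1:3, ph[1:3], ph[2:4])
    }
    length(intersect(b(w1), b(w2)))
  }
  best <- NULL; best_pp <- -Inf
  for (sel in utils::combn(nrow(pool), k, simplify = FALSE)) {
    ok <- all(utils::combn(sel, 2, function(ij) {
      shares(pool$word[ij[1]], pool$word[ij[2]]) == 0
    }))
    if (ok && sum(pool$pp[sel]) > best_pp) {
      best_pp <- sum(pool$pp[sel]); best <- pool$word[sel]
    }
  }
  expect_identical(sort(vapply(strict$words, function(w)
    paste(w$phonemes, collapse = " "), character(1))), sort(best))
})

test_that("recombination reuses PP+ material at lower but still high mean pp", {
  inv <- toy_inventory()
  lex <- toy_lexicon()
  tab <- biphone_table(lex)
  cand <- generate_candidates(tab, inv, lex)
  plus <- select_top_set(cand, tab,
                         constraints = list(max_shared_biphones = 0,
                                            max_initial_repeats = 2),
                         lexicon = lex)
  for (mode in c("syllable", "biphone")) {
    minus <- recombine_biphones(plus, tab, inv, lex, mode = mode)
    expect_identical(minus$label, "PP_minus")
    expect_length(minus$words, 6L)
    expect_lt(minus$mean_pp, plus$mean_pp)
    expect_gte(minus$mean_pp, 0.75 * plus$mean_pp)
    all_keys <- vapply(c(plus$words, minus$words), function(w)
      paste(w$phonemes, collapse = " "), character(1))
    expect_length(unique(all_keys), 12L)          # mutually distinct
    lex_keys <- vapply(lex$phonemes, paste, character(1), collapse = " ")
    expect_false(any(all_keys %in% lex_keys))     # all novel
    if (mode == "syllable") {
      # every PP- word is built from PP+ CV syllables
      syll <- unlist(lapply(plus$words, function(w) {
        c(paste(w$phonemes[1:2], collapse = " "),
          paste(w$phonemes[3:4], collapse = " "))
      }))
      for (w in minus$words) {
        expect_true(paste(w$phonemes[1:2], collapse = " ") %in% syll)
        expect_true(paste(w$phonemes[3:4], collapse = " ") %in% syll)
      }
    }
  }
  # determinism: the search is RNG-free
  minus1 <- recombine_biphones(plus, tab, inv, lex)
  minus2 <- recombine_biphones(plus, tab, inv, lex)
  expect_identical(vapply(minus1$words, function(w) w$pp, numeric(1)),
                   vapply(minus2$words, function(w) w$pp, numeric(1)))
})

test_that("recombination fails when all biphones are equiprobable (mean cannot drop)", {
  inv <- phoneme_inventory(c("b", "t", "a", "o"),
                           c("consonant", "consonant", "vowel", "vowel"))
  # symmetric lexicon: every attested biphone has probability 1/4 per position
  lex <- as_lexicon(c("b a t o a" = 10L, "t o b a a" = 10L,
                      "b o t a a" = 10L, "t a b o a" = 10L), inv)
  tab <- biphone_table(lex)
  cand <- generate_candidates(tab, inv, lex)
  expect_true(all(abs(cand$pp - cand$pp[1]) < 1e-12))
  plus <- select_top_set(cand, tab, k = 2, lexicon = lex)
  expect_error(recombine_biphones(plus, tab, inv, lex, k = 2),
               "strictly below")
})

test_that("stimulus sets enforce distinctness and novelty", {
  inv <- tiny_inventory()
  lex <- demo_lexicon()
  tab <- biphone_table(lex)
  w1 <- score_word(c("b", "a", "t", "o"), tab)
  w2 <- score_word(c("k", "o", "m", "a"), tab)
  s <- stimulus_set(list(w1, w2), "PP_plus", lexicon = lex)
  expect_equal(s$mean_pp, mean(c(w1$pp, w2$pp)))
  expect_error(stimulus_set(list(w1, w1), "PP_plus"), "distinct")
  in_lex <- score_word(c("b", "a", "t", "a"), tab)
  expect_error(stimulus_set(list(in_lex), "PP_plus", lexicon = lex), "novel")
})
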
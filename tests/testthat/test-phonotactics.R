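test_that("biphone probabilities follow the log-frequency weighting formula", {
  inv <- tiny_inventory()
  # both words share b-a at position 1: (log10 100 + log10 10)/(same) = 1
  lex <- as_lexicon(c("b a t a" = 100L, "b a b o" = 10L), inv)
  tab <- biphone_table(lex)
  expect_equal(biphone_prob(tab, 1, "b", "a"), 1.0)
  # split numerators: 2/(2+1) and 1/(2+1)
  lex2 <- as_lexicon(c("b a t a" = 100L, "t a b o" = 10L), inv)
  tab2 <- biphone_table(lex2)
  expect_equal(biphone_prob(tab2, 1, "b", "a"), 2 / 3)
  expect_equal(biphone_prob(tab2, 1, "t", "a"), 1 / 3)
  expect_equal(biphone_prob(tab2, 1, "b", "a") +
                 biphone_prob(tab2, 1, "t", "a"), 1)
  # single-word lexicon: every biphone of that word has probability 1
  tab3 <- biphone_table(as_lexicon(c("k o t a" = 500L), inv))
  expect_equal(tab3$prob$probability, rep(1, 3))
  expect_error(biphone_table(as_lexicon(c("b a" = 1L)[0], inv)), "empty")
})

test_that("each position's probabilities sum to one and denominators are exposed", {
  for (s in 1:5) {
    lex <- random_lexicon(seed = 100 + s, n_words = 15)
    tab <- biphone_table(lex)
    sums <- tapply(tab$prob$probability, tab$prob$position, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(tab$prob$denominator > 0))
    expect_true(all(tab$prob$probability >= 0 & tab$prob$probability <= 1))
  }
})

test_that("table matches an independent brute-force oracle to 1e-12", {
  for (s in 1:20) {
    lex <- random_lexicon(seed = 200 + s, n_words = sample(3:20, 1))
    tab <- biphone_table(lex)
    oracle <- oracle_biphone_table(lex)
    for (i in seq_len(nrow(tab$prob))) {
      key <- paste(tab$prob$position[i], tab$prob$ph1[i], tab$prob$ph2[i])
      expect_equal(tab$prob$probability[i], oracle[[key]], tolerance = 1e-12)
    }
    expect_equal(length(oracle), nrow(tab$prob))
  }
})

test_that("log weighting is not scale invariant: rescaled frequencies recompute exactly", {
  lex <- demo_lexicon()
  tab1 <- biphone_table(lex)
  lex10 <- lex
  lex10$frequency <- lex10$frequency * 10L
  tab10 <- biphone_table(lex10)
  expect_false(isTRUE(all.equal(tab1$prob$probability, tab10$prob$probability)))
  oracle10 <- oracle_biphone_table(lex10)
  for (i in seq_len(nrow(tab10$prob))) {
    key <- paste(tab10$prob$position[i], tab10$prob$ph1[i], tab10$prob$ph2[i])
    expect_equal(tab10$prob$probability[i], oracle10[[key]], tolerance = 1e-12)
  }
})

test_that("word scoring aggregates biphone probabilities and flags unseen pairs", {
  inv <- tiny_inventory()
  lex <- as_lexicon(c("k o t a" = 500L), inv)
  tab <- biphone_table(lex)
  # scoring the lexicon's only word with mean aggregation gives 1
  expect_equal(score_word(c("k", "o", "t", "a"), tab, "mean")$pp, 1.0)
  expect_equal(score_word(c("k", "o", "t", "a"), tab, "sum")$pp, 3.0)
  # a fully unseen word scores 0 and is flagged
  w <- score_word(c("b", "i", "m", "u"), tab)
  expect_equal(w$pp, 0)
  expect_true(w$all_unseen)
  expect_false(score_word(c("k", "o", "t", "a"), tab)$all_unseen)
  expect_error(score_word("k", tab), "shorter than 2")
  # monotonicity: replacing one biphone by a strictly more probable one raises pp
  lex2 <- demo_lexicon()
  tab2 <- biphone_table(lex2)
  p_ba <- biphone_prob(tab2, 1, "b", "a")
  p_ta <- biphone_prob(tab2, 1, "t", "a")
  expect_true(p_ba > p_ta)
  hi <- score_word(c("b", "a", "t", "a"), tab2)$pp
  lo <- score_word(c("t", "a", "t", "a"), tab2)$pp
  expect_equal(hi - lo, p_ba - p_ta)
  expect_gt(hi, lo)
  expect_equal(oracle_score(c("b", "a", "t", "a"), oracle_biphone_table(lex2)),
               hi, tolerance = 1e-12)
})

test_that("set mean reproduces the published per-set values", {
  st <- study_stimuli()
  expect_equal(round(set_mean_pp(st$pp[st$set_label == "PP_plus"]), 4), 0.0085)
  expect_equal(round(set_mean_pp(st$pp[st$set_label == "PP_minus"]), 4), 0.0073)
  expect_equal(set_mean_pp(rep(0.42, 6)), 0.42)
  expect_error(set_mean_pp(numeric(0)), "empty")
})

test_that("biphone table TSV serialization round-trips", {
  tab <- biphone_table(demo_lexicon())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_biphone_table(tab, f)
  back <- read_biphone_table(f)
  expect_equal(back$prob$probability, tab$prob$probability)
  expect_equal(back$prob$denominator, tab$prob$denominator)
  expect_equal(biphone_prob(back, 1, "b", "a"), biphone_prob(tab, 1, "b", "a"))
})
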
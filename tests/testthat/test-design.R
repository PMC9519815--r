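test_that("counterbalancing swaps object blocks across sets", {
  words <- sprintf("w%02d", 1:12)
  sets <- rep(c("PP_plus", "PP_minus"), each = 6)
  objs <- sprintf("o%02d", 1:12)
  A <- counterbalance_assignment(words, sets, objs, "A", seed = 9)
  A2 <- counterbalance_assignment(words, sets, objs, "A", seed = 9)
  B <- counterbalance_assignment(words, sets, objs, "B", seed = 9)
  expect_identical(A, A2)                               # seeded determinism
  expect_identical(A$set_label, B$set_label)            # words keep their set
  set_of_obj_A <- stats::setNames(A$set_label, A$object_id)
  set_of_obj_B <- stats::setNames(B$set_label, B$object_id)
  expect_true(all(set_of_obj_A[names(set_of_obj_B)] != set_of_obj_B))
  expect_length(intersect(paste(A$word_id, A$object_id),
                          paste(B$word_id, B$object_id)), 0L)
  expect_error(counterbalance_assignment(words[1:10], sets[1:10], objs, "A"),
               "equal length")
})

test_that("pairing schedule: all distinct pairings plus one perfect matching", {
  labels <- sprintf("p%d", 1:6)
  sched <- build_pairing_schedule(labels, exposures = 6, seed = 3)
  expect_equal(nrow(sched), 18L)
  appearances <- table(c(sched$a, sched$b))
  expect_true(all(appearances == 6L))
  # the 15 distinct unordered pairings all appear; 3 appear twice
  key <- apply(cbind(pmin(sched$a, sched$b), pmax(sched$a, sched$b)), 1,
               paste, collapse = "|")
  expect_length(unique(key), 15L)
  expect_equal(as.integer(sort(table(key), decreasing = TRUE)[1:3]),
               rep(2L, 3))
  # per-label distinct partners: 5 (each label meets all others)
  partners <- lapply(labels, function(l) {
    unique(c(sched$b[sched$a == l], sched$a[sched$b == l]))
  })
  expect_true(all(lengths(partners) == 5L))
  expect_identical(nrow(build_pairing_schedule(c("x", "y"), 1)), 1L)
  expect_error(build_pairing_schedule(labels[1:3], 3), "even|matching")
})

test_that("generated designs satisfy the published counts, timing and balance", {
  des <- generate_design(design_spec(seed = 5))
  expect_equal(nrow(des$training), 36L)
  expect_equal(as.integer(table(des$training$set_label)), c(18L, 18L))
  expect_equal(nrow(des$test), 24L)
  expect_equal(nrow(des$warmup), 2L)
  expect_equal(sum(des$test$repetition == 1), 12L)
  # each pair probed exactly twice
  expect_true(all(table(des$test$pair_id) == 2L))
  # trial component timings sum to ~4 s
  timing <- des$training[1, c("t_silence_ms", "t_word1_ms", "t_pause_ms",
                              "t_word2_ms", "t_trailing_ms")]
  expect_equal(sum(unlist(timing)), 950 + 696 + 700 + 696 + 950)
  expect_equal(sum(unlist(timing)), 3992)
  # words of a trial label exactly its two objects; sets never mixed
  ref <- stats::setNames(des$pairs$object_id, des$pairs$word_id)
  set_of_obj <- stats::setNames(des$pairs$set_label, des$pairs$object_id)
  for (i in seq_len(36)) {
    tr <- des$training[i, ]
    expect_setequal(ref[c(tr$first_word, tr$second_word)],
                    c(tr$left_object, tr$right_object))
    expect_identical(unname(set_of_obj[tr$left_object]), tr$set_label)
    expect_identical(unname(set_of_obj[tr$right_object]), tr$set_label)
  }
  # object side carries no information about word order: exactly half the
  # trials have the first-played word's referent on the left
  expect_equal(sum(des$training$first_referent_side == "left"), 18L)
  # test trials never mix sets and target sits in a balanced corner
  for (i in seq_len(24)) {
    tt <- des$test[i, ]
    shown <- c(tt$obj_ul, tt$obj_ur, tt$obj_ll, tt$obj_lr)
    expect_length(unique(shown), 4L)
    expect_true(all(set_of_obj[shown] == tt$set_label))
    expect_true(tt$target_object %in% shown)
  }
  corner_counts <- table(des$test$target_position, des$test$set_label)
  expect_true(all(corner_counts == 3L))
})

test_that("design invariants hold across seeds and interleave policies", {
  for (s in c(1, 7, 23, 48, 91)) {
    des <- generate_design(design_spec(seed = s))
    expect_no_violations(des)
    rep_ <- validate_design(des)
    expect_equal(rep_$diag_min, 6)
    expect_lte(rep_$offdiag_max, 2)
    expect_equal(rep_$cross_set_max, 0)
    # co-occurrence separability guaranteeing the ideal learner
    expect_gte(rep_$diag_min / max(rep_$offdiag_max, 1), 3)
    runs <- rle(des$training$set_label)
    expect_lte(max(runs$lengths), 2L)
  }
  alt <- generate_design(design_spec(seed = 3, interleave = "alternate"))
  expect_true(all(rle(alt$training$set_label)$lengths == 1L))
  expect_no_violations(alt)
})

test_that("foil appearances are balanced within each set", {
  des <- generate_design(design_spec(seed = 31))
  for (lab in c("PP_plus", "PP_minus")) {
    sub <- des$test[des$test$set_label == lab, ]
    shown <- c(sub$obj_ul, sub$obj_ur, sub$obj_ll, sub$obj_lr)
    foil <- table(shown) - table(factor(sub$target_object,
                                        levels = names(table(shown))))
    expect_lte(max(foil) - min(foil), 1L)
    expect_equal(sum(foil), 36L)   # 12 trials x 3 foils
  }
})

test_that("an empty design yields an empty report", {
  rep_ <- validate_design(list(training = NULL, test = NULL, pairs = NULL))
  expect_identical(rep_$violations, character(0))
  expect_equal(length(rep_$cooccurrence), 0L)
})
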
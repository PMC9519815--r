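#' Design specification for a two-set CSWL experiment
#'
#' Parameters of the cross-situational word learning design: 6 word-object
#' pairs per set, 6 ambiguous 2x2 exposures per pair (36 training trials),
#' and 2 four-alternative forced-choice test repetitions per pair (24 test
#' trials), with interleaved presentation of the two sets.
#'
#' @param pairs_per_set pairs per stimulus set (default 6).
#' @param exposures_per_pair training exposures per pair (default 6).
#' @param test_repetitions test probes per pair (default 2).
#' @param interleave \code{"max_run"} (seeded order with at most
#'   \code{max_run} consecutive same-set trials) or \code{"alternate"}
#'   (strict alternation).
#' @param max_run maximum run of consecutive same-set training trials.
#' @param counterbalance_version \code{"A"} or \code{"B"}.
#' @param seed integer seed driving all randomized choices.
#' @return list of class \code{design_spec}.
#' @export
design_spec <- function(pairs_per_set = 6, exposures_per_pair = 6,
                        test_repetitions = 2,
                        interleave = c("max_run", "alternate"), max_run = 2,
                        counterbalance_version = c("A", "B"), seed = 1L) {
  interleave <- match.arg(interleave)
  counterbalance_version <- match.arg(counterbalance_version)
  if ((pairs_per_set * exposures_per_pair) %% 2L != 0L) {
    stop("pairs_per_set * exposures_per_pair must be even (two pairs per trial)")
  }
  structure(list(pairs_per_set = pairs_per_set,
                 exposures_per_pair = exposures_per_pair,
                 test_repetitions = test_repetitions,
                 interleave = interleave, max_run = max_run,
                 counterbalance_version = counterbalance_version,
                 seed = as.integer(seed)),
            class = "design_spec")
}

# trial timing constants (ms): silence, word, pause, word, trailing pause
TRIAL_TIMING <- c(silence = 950, word1 = 696, pause = 700, word2 = 696,
                  trailing = 950)

#' Counterbalanced word-object pair assignment
#'
#' Version A pairs the 12 words with the 12 objects at random (seeded).
#' Version B reuses version A's word order but swaps the object blocks
#' between the two sets, so every word keeps its set while every object
#' changes set: A and B share no (word, object) pair.
#'
#' @param word_ids character vector of 12 word ids.
#' @param set_labels character vector parallel to \code{word_ids}
#'   (\code{"PP_plus"}/\code{"PP_minus"}, 6 each).
#' @param object_ids character vector of 12 object ids.
#' @param version \code{"A"} or \code{"B"}.
#' @param seed integer seed.
#' @return data.frame \code{pair_id, word_id, object_id, set_label}.
#' @export
counterbalance_assignment <- function(word_ids, set_labels, object_ids,
                                      version = c("A", "B"), seed = 1L) {
  version <- match.arg(version)
  n <- length(word_ids)
  if (length(set_labels) != n || length(object_ids) != n) {
    stop("word_ids, set_labels and object_ids must have equal length")
  }
  if (anyDuplicated(word_ids) || anyDuplicated(object_ids)) {
    stop("word and object ids must be unique")
  }
  tab <- table(set_labels)
  if (length(tab) != 2L || length(unique(as.integer(tab))) != 1L) {
    stop("set_labels must split the words into two equal sets")
  }
  set.seed(seed)
  objects <- sample(object_ids)
  if (version == "B") {
    sets <- unique(set_labels)
    in1 <- set_labels == sets[1]
    swapped <- objects
    swapped[in1] <- objects[!in1]
    swapped[!in1] <- objects[in1]
    objects <- swapped
  }
  data.frame(pair_id = paste0("pair_", sprintf("%02d", seq_len(n))),
             word_id = word_ids, object_id = objects, set_label = set_labels,
             stringsAsFactors = FALSE)
}

#' Pairing schedule: which labels co-occur on each training trial
#'
#' For n labels with e exposures each (two labels per trial), constructs the
#' multiset of unordered label pairs. For e = n - 1 this is the round robin
#' of all distinct pairs; for e = n (the study's 6 labels x 6 exposures) it
#' is all C(n,2) distinct pairs plus one seeded perfect matching, so each
#' label appears exactly e times and meets all n - 1 partners.
#'
#' @param labels character vector of pair ids for one set.
#' @param exposures exposures per label.
#' @param seed integer seed for the perfect matching.
#' @return data.frame \code{a, b}, one row per trial pairing.
#' @export
build_pairing_schedule <- function(labels, exposures = 6, seed = 1L) {
  n <- length(labels)
  if (n < 2L) stop("need at least 2 labels")
  if ((n * exposures) %% 2L != 0L) {
    stop("infeasible: total label appearances (n * exposures) must be even")
  }
  extra <- exposures - (n - 1L)
  if (extra < 0L) stop("exposures below n - 1 not supported (labels could not meet all partners)")
  if (extra > 1L) stop("exposures above n not supported")
  if (extra == 1L && n %% 2L != 0L) stop("perfect matching needs an even number of labels")
  cmb <- utils::combn(labels, 2L)
  out <- data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
  if (extra == 1L) {
    set.seed(seed)
    perm <- sample(labels)
    out <- rbind(out, data.frame(
      a = perm[seq(1L, n, by = 2L)], b = perm[seq(2L, n, by = 2L)],
      stringsAsFactors = FALSE))
  }
  out
}

# interleave two equally long blocks with runs of at most max_run; greedy with
# feasibility lookahead (never leave one set needing runs longer than max_run)
interleave_sets <- function(n_each, max_run = 2L) {
  counts <- c(A = n_each, B = n_each)
  out <- character(2L * n_each)
  run <- 0L; last <- ""
  # after placing `o` (new run length run_o), the rest is completable iff the
  # other set can separate o's remainder (<= max_run per slot, the slot
  # touching the current run shortened by run_o) and vice versa
  completable <- function(cc, o, run_o) {
    other <- setdiff(names(cc), o)
    cc[[o]] <= max_run * (cc[[other]] + 1L) - run_o &&
      cc[[other]] <= max_run * (cc[[o]] + 1L)
  }
  for (i in seq_along(out)) {
    opts <- names(counts)[counts > 0L]
    if (run >= max_run) opts <- setdiff(opts, last)
    feas <- vapply(opts, function(o) {
      cc <- counts; cc[o] <- cc[o] - 1L
      completable(cc, o, if (o == last) run + 1L else 1L)
    }, logical(1))
    opts <- opts[feas]
    if (!length(opts)) stop("interleaving infeasible for max_run = ", max_run)
    pick <- if (length(opts) == 1L) opts else sample(opts, 1L)
    out[i] <- pick
    counts[pick] <- counts[pick] - 1L
    run <- if (pick == last) run + 1L else 1L
    last <- pick
  }
  out
}

#' Assemble the training phase
#'
#' Orders the two sets' pairing schedules into a single interleaved trial
#' sequence (never mixing sets within a trial), randomizes which pair's word
#' is played first and on which side each referent appears, and balances the
#' side of the first-played word's referent to exactly half the trials so
#' object position carries no information about word order. Component
#' timings per trial: 950 ms silence, ~696 ms word, 700 ms pause, ~696 ms
#' word, 950 ms trailing pause (~4 s).
#'
#' @param schedule_plus,schedule_minus pairing schedules
#'   (\code{\link{build_pairing_schedule}}) for the PP+ and PP- sets, in
#'   pair ids.
#' @param pairs the word-object assignment
#'   (\code{\link{counterbalance_assignment}}).
#' @param spec a \code{\link{design_spec}}.
#' @return data.frame of training trials: \code{index, set_label,
#'   left_object, right_object, first_word, second_word,
#'   first_referent_side}, plus the five timing columns (ms).
#' @export
assemble_training_trials <- function(schedule_plus, schedule_minus, pairs,
                                     spec = design_spec()) {
  set.seed(spec$seed + 101L)
  n_each <- nrow(schedule_plus)
  if (nrow(schedule_minus) != n_each) stop("schedules must be equally long")
  order_tag <- if (spec$interleave == "alternate") {
    rep(sample(c("A", "B")), n_each)
  } else {
    interleave_sets(n_each, spec$max_run)
  }
  sched <- list(A = schedule_plus[sample(n_each), , drop = FALSE],
                B = schedule_minus[sample(n_each), , drop = FALSE])
  label_of <- c(A = "PP_plus", B = "PP_minus")
  n <- 2L * n_each
  # balanced: first-played word's referent on the left in exactly half the trials
  first_left <- sample(rep(c(TRUE, FALSE), length.out = n))
  ptr <- c(A = 0L, B = 0L)
  rows <- vector("list", n)
  obj_of <- stats::setNames(pairs$object_id, pairs$pair_id)
  word_of <- stats::setNames(pairs$word_id, pairs$pair_id)
  for (i in seq_len(n)) {
    s <- order_tag[i]
    ptr[s] <- ptr[s] + 1L
    pr <- sched[[s]][ptr[s], ]
    two <- sample(c(pr$a, pr$b))            # which pair's word plays first
    first <- two[1]; second <- two[2]
    left <- if (first_left[i]) first else second
    right <- setdiff(two, left)
    rows[[i]] <- data.frame(
      index = i, set_label = label_of[[s]],
      left_object = obj_of[[left]], right_object = obj_of[[right]],
      first_word = word_of[[first]], second_word = word_of[[second]],
      first_referent_side = if (first_left[i]) "left" else "right",
      t_silence_ms = TRIAL_TIMING[["silence"]],
      t_word1_ms = TRIAL_TIMING[["word1"]],
      t_pause_ms = TRIAL_TIMING[["pause"]],
      t_word2_ms = TRIAL_TIMING[["word2"]],
      t_trailing_ms = TRIAL_TIMING[["trailing"]],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# repair pass: swap foils between objects until per-set appearance counts
# differ by at most 1 (greedy picking alone can get stuck on the last trials
# because a trial's target cannot serve as its own foil)
rebalance_foils <- function(test) {
  obj_cols <- c("obj_ul", "obj_ur", "obj_ll", "obj_lr")
  for (lab in unique(test$set_label)) {
    idx <- which(test$set_label == lab)
    foil_count <- function() {
      shown <- unlist(test[idx, obj_cols], use.names = FALSE)
      tab <- table(shown) - table(factor(test$target_object[idx],
                                         levels = names(table(shown))))
      stats::setNames(as.integer(tab), names(tab))
    }
    for (iter in seq_len(200L)) {
      fc <- foil_count()
      if (max(fc) - min(fc) <= 1L) break
      hi <- names(fc)[which.max(fc)]
      done <- FALSE
      for (t in sample(idx)) {
        shown <- unlist(test[t, obj_cols], use.names = FALSE)
        if (!hi %in% shown || test$target_object[t] == hi) next
        absent <- setdiff(names(fc), shown)
        absent <- absent[fc[absent] <= fc[hi] - 2L]
        if (!length(absent)) next
        lo <- absent[which.min(fc[absent])]
        col <- obj_cols[match(hi, shown)]
        test[t, col] <- lo
        done <- TRUE
        break
      }
      if (!done) stop("could not rebalance foil counts in set ", lab)
    }
  }
  test
}

# seeded balanced sampling: pick k items keeping running counts within 1
balanced_pick <- function(items, k, counts) {
  picked <- character(0)
  for (j in seq_len(k)) {
    pool <- setdiff(items, picked)
    low <- pool[counts[pool] == min(counts[pool])]
    p <- if (length(low) == 1L) low else sample(low, 1L)
    picked <- c(picked, p)
    counts[p] <- counts[p] + 1L
  }
  list(picked = picked, counts = counts)
}

#' Build the 4AFC test phase
#'
#' Each word-object pair is probed \code{test_repetitions} times (default
#' twice, 24 trials); repetition-1 probes all precede repetition-2 probes.
#' Each trial shows four objects from the probe's own set only: the target
#' plus 3 foils drawn from the remaining 5 same-set objects by seeded
#' balanced sampling (within a set, foil appearance counts differ by at most
#' 1). The target's corner is balanced across the four screen positions.
#' Two warm-up trials with known everyday objects precede the test proper.
#'
#' @param pairs the word-object assignment.
#' @param spec a \code{\link{design_spec}}.
#' @return list with \code{test} (data.frame: \code{index, set_label,
#'   obj_ul, obj_ur, obj_ll, obj_lr, probe_word, target_object,
#'   target_position, repetition}) and \code{warmup} (2 rows, same shape,
#'   known-object placeholders).
#' @export
build_test_trials <- function(pairs, spec = design_spec()) {
  set.seed(spec$seed + 202L)
  corners <- c("UL", "UR", "LL", "LR")
  sets <- split(pairs, pairs$set_label)
  trials <- list()
  for (lab in names(sets)) {
    px <- sets[[lab]]
    objs <- px$object_id
    foil_counts <- stats::setNames(rep(0L, length(objs)), objs)
    n_trials <- nrow(px) * spec$test_repetitions
    # target corner balanced within each set
    corner_seq <- sample(rep(corners, length.out = n_trials))
    ti <- 0L
    for (rep_i in seq_len(spec$test_repetitions)) {
      for (r in sample(nrow(px))) {
        ti <- ti + 1L
        target <- px$object_id[r]
        bp <- balanced_pick(setdiff(objs, target), 3L, foil_counts)
        foil_counts <- bp$counts
        corner <- corner_seq[ti]
        slot <- stats::setNames(rep(NA_character_, 4L), corners)
        slot[corner] <- target
        slot[is.na(slot)] <- sample(bp$picked)
        trials[[length(trials) + 1L]] <- data.frame(
          set_label = lab, obj_ul = slot[["UL"]], obj_ur = slot[["UR"]],
          obj_ll = slot[["LL"]], obj_lr = slot[["LR"]],
          probe_word = px$word_id[r], target_object = target,
          target_position = corner, repetition = rep_i,
          pair_id = px$pair_id[r], stringsAsFactors = FALSE)
      }
    }
  }
  test <- do.call(rbind, trials)
  test <- rebalance_foils(test)
  # all repetition-1 probes first, order shuffled within repetition blocks
  test <- test[order(test$repetition, sample(nrow(test))), , drop = FALSE]
  test$index <- seq_len(nrow(test))
  rownames(test) <- NULL
  known <- c("house", "duck", "ball", "cat")
  warm <- lapply(1:2, function(i) {
    arr <- sample(known)
    tgt <- sample(known, 1L)
    data.frame(set_label = "warmup", obj_ul = arr[1], obj_ur = arr[2],
               obj_ll = arr[3], obj_lr = arr[4], probe_word = tgt,
               target_object = tgt,
               target_position = corners[match(tgt, arr)], repetition = 0L,
               pair_id = NA_character_, index = i, stringsAsFactors = FALSE)
  })
  list(test = test, warmup = do.call(rbind, warm))
}

#' Generate a complete CSWL design
#'
#' Convenience wrapper: counterbalanced pair assignment, per-set pairing
#' schedules, interleaved training trials, and the 4AFC test phase.
#'
#' @param word_ids,set_labels,object_ids as in
#'   \code{\link{counterbalance_assignment}}; defaults use generic ids
#'   (\code{w01..w12} / \code{o01..o12}, 6 pairs per set).
#' @param spec a \code{\link{design_spec}}.
#' @return list of class \code{cswl_design}: \code{pairs}, \code{training},
#'   \code{test}, \code{warmup}, \code{spec}.
#' @export
generate_design <- function(spec = design_spec(),
                            word_ids = sprintf("w%02d", 1:(2 * spec$pairs_per_set)),
                            set_labels = rep(c("PP_plus", "PP_minus"),
                                             each = spec$pairs_per_set),
                            object_ids = sprintf("o%02d", 1:(2 * spec$pairs_per_set))) {
  pairs <- counterbalance_assignment(word_ids, set_labels, object_ids,
                                     version = spec$counterbalance_version,
                                     seed = spec$seed)
  ids <- split(pairs$pair_id, pairs$set_label)
  sp <- build_pairing_schedule(ids$PP_plus, spec$exposures_per_pair,
                               seed = spec$seed + 11L)
  sm <- build_pairing_schedule(ids$PP_minus, spec$exposures_per_pair,
                               seed = spec$seed + 12L)
  training <- assemble_training_trials(sp, sm, pairs, spec)
  tst <- build_test_trials(pairs, spec)
  structure(list(pairs = pairs, training = training, test = tst$test,
                 warmup = tst$warmup, spec = spec),
            class = "cswl_design")
}

#' @export
print.cswl_design <- function(x, ...) {
  cat(sprintf("<cswl_design> %d pairs (%d per set), %d training trials, %d test trials (+%d warm-up)\n",
              nrow(x$pairs), x$spec$pairs_per_set, nrow(x$training),
              nrow(x$test), nrow(x$warmup)))
  invisible(x)
}

#' Validate a design: co-occurrence and balance report
#'
#' Computes the word-by-object training co-occurrence matrix (a word
#' co-occurs with both objects of every trial it is played in), per-set foil
#' appearance counts and target-corner counts at test, the word-order/side
#' balance, and a list of violated design constraints. An ideal co-occurrence
#' learner is guaranteed correct whenever the minimum diagonal count exceeds
#' every off-diagonal count.
#'
#' @param design a \code{cswl_design} (or a list with \code{pairs},
#'   \code{training}, \code{test}).
#' @return list of class \code{design_report}: \code{cooccurrence},
#'   \code{diag_min}, \code{offdiag_max}, \code{cross_set_max},
#'   \code{foil_counts}, \code{corner_counts}, \code{n_first_referent_left},
#'   \code{violations} (character vector, empty when the design is valid).
#' @export
validate_design <- function(design) {
  empty <- is.null(design$training) || !nrow(design$training)
  if (empty) {
    return(structure(list(cooccurrence = matrix(0, 0, 0), diag_min = NA,
                          offdiag_max = NA, cross_set_max = NA,
                          foil_counts = integer(0), corner_counts = integer(0),
                          n_first_referent_left = 0L, violations = character(0)),
                     class = "design_report"))
  }
  pairs <- design$pairs
  M <- train_associative(design$training, pairs)
  set_of_word <- stats::setNames(pairs$set_label, pairs$word_id)
  set_of_obj <- stats::setNames(pairs$set_label, pairs$object_id)
  ref_of_word <- stats::setNames(pairs$object_id, pairs$word_id)
  dg <- vapply(rownames(M), function(w) M[w, ref_of_word[[w]]], numeric(1))
  off <- M
  for (w in rownames(M)) off[w, ref_of_word[[w]]] <- NA
  same_set <- outer(set_of_word[rownames(M)], set_of_obj[colnames(M)], "==")
  offdiag_max <- suppressWarnings(max(off[same_set], na.rm = TRUE))
  cross_set_max <- max(M[!same_set])
  violations <- character(0)
  spec <- design$spec %||% design_spec()
  if (any(dg != spec$exposures_per_pair)) {
    violations <- c(violations, "diagonal co-occurrence != exposures_per_pair")
  }
  if (cross_set_max > 0) violations <- c(violations, "cross-set co-occurrence > 0")
  if (min(dg) <= offdiag_max) {
    violations <- c(violations, "diagonal does not dominate off-diagonal")
  }
  nleft <- sum(design$training$first_referent_side == "left")
  n <- nrow(design$training)
  if (abs(nleft - n / 2) > 1) {
    violations <- c(violations, "first-played word's referent side unbalanced")
  }
  foil_counts <- integer(0); corner_counts <- integer(0)
  if (!is.null(design$test) && nrow(design$test)) {
    tst <- design$test
    for (lab in unique(tst$set_label)) {
      sub <- tst[tst$set_label == lab, ]
      shown <- c(sub$obj_ul, sub$obj_ur, sub$obj_ll, sub$obj_lr)
      fc <- table(shown[!shown %in% NA]) - table(factor(sub$target_object,
                                                        levels = names(table(shown))))
      fc <- as.integer(fc); names(fc) <- paste(lab, names(table(shown)))
      foil_counts <- c(foil_counts, fc)
      if (max(fc) - min(fc) > 1L) {
        violations <- c(violations, paste0("foil counts unbalanced in ", lab))
      }
      cc <- table(sub$target_position)
      corner_counts <- c(corner_counts, stats::setNames(as.integer(cc),
                                                        paste(lab, names(cc))))
      mixed <- apply(sub[, c("obj_ul", "obj_ur", "obj_ll", "obj_lr")], 1L,
                     function(o) any(set_of_obj[o] != lab))
      if (any(mixed)) violations <- c(violations, paste0("mixed-set test trial in ", lab))
    }
  }
  structure(list(cooccurrence = M, diag_min = min(dg), offdiag_max = offdiag_max,
                 cross_set_max = cross_set_max, foil_counts = foil_counts,
                 corner_counts = corner_counts, n_first_referent_left = nleft,
                 violations = violations),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("<design_report>\n")
  if (!length(x$cooccurrence)) { cat("  (empty design)\n"); return(invisible(x)) }
  cat(sprintf("  co-occurrence: diag min %s, within-set off-diag max %s, cross-set max %s\n",
              x$diag_min, x$offdiag_max, x$cross_set_max))
  cat(sprintf("  first-referent-left trials: %d\n", x$n_first_referent_left))
  if (length(x$violations)) {
    cat("  VIOLATIONS:\n"); for (v in x$violations) cat("   -", v, "\n")
  } else cat("  no violations\n")
  invisible(x)
}
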
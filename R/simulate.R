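#' Participant / cohort simulation configuration
#'
#' Three learner mechanisms are available. \code{"glmm_generative"} (the
#' default) is the generative counterpart of the analysis model: the
#' probability of a correct 4AFC choice is
#' \deqn{P(correct) = logit^{-1}(logit(0.25) + \beta_0 + \delta \cdot [set = PP+] + u_p + u_s)}
#' with participant and stimulus random effects
#' \eqn{u_p \sim N(0, \tau_p^2)}, \eqn{u_s \sim N(0, \tau_s^2)}; incorrect
#' choices are uniform over the 3 foils. \code{"associative"} is a
#' mechanism-level co-occurrence learner (count matrix + softmax choice with
#' optional lapses); \code{"guesser"} chooses uniformly.
#'
#' Defaults reproduce the study conditions: 6+6 pairs, above-chance log-odds
#' \code{beta0 = log(7.61)}, PP-set effect \code{delta = log(1.19)}, random
#' effect SDs \code{sqrt(2.35)} (participants) and \code{sqrt(0.21)}
#' (stimuli). Reaction times are lognormal (meanlog \code{log(1200)}, sdlog
#' 0.35) with a 2\% uniform far-tail contamination component (10--30 s),
#' emulating the distraction trials the 3-SD rule is meant to remove.
#'
#' @param learner one of \code{"glmm_generative"}, \code{"associative"},
#'   \code{"guesser"}.
#' @param softmax_temperature softmax temperature for the associative
#'   learner; 0 means argmax (ties broken at random).
#' @param lapse_rate probability of a uniform random choice.
#' @param beta0 above-chance log-odds (reference set).
#' @param delta_pp_plus additional log-odds for the PP+ set.
#' @param tau_participant,tau_stimulus random-effect SDs (>= 0).
#' @param rt_log_mean,rt_log_sd lognormal RT parameters (ms scale).
#' @param contamination_rate probability an RT is replaced by a far outlier.
#' @param contamination_range range (ms) of contaminated RTs.
#' @param seed integer seed.
#' @return list of class \code{participant_config}.
#' @export
participant_config <- function(learner = c("glmm_generative", "associative",
                                           "guesser"),
                               softmax_temperature = 1, lapse_rate = 0,
                               beta0 = log(7.61), delta_pp_plus = log(1.19),
                               tau_participant = sqrt(2.35),
                               tau_stimulus = sqrt(0.21),
                               rt_log_mean = log(1200), rt_log_sd = 0.35,
                               contamination_rate = 0.02,
                               contamination_range = c(10000, 30000),
                               seed = 1L) {
  learner <- match.arg(learner)
  stopifnot(softmax_temperature >= 0, lapse_rate >= 0, lapse_rate <= 1,
            tau_participant >= 0, tau_stimulus >= 0, rt_log_sd >= 0,
            contamination_rate >= 0, contamination_rate <= 1)
  structure(list(learner = learner, softmax_temperature = softmax_temperature,
                 lapse_rate = lapse_rate, beta0 = beta0,
                 delta_pp_plus = delta_pp_plus,
                 tau_participant = tau_participant,
                 tau_stimulus = tau_stimulus, rt_log_mean = rt_log_mean,
                 rt_log_sd = rt_log_sd, contamination_rate = contamination_rate,
                 contamination_range = contamination_range,
                 seed = as.integer(seed)),
            class = "participant_config")
}

#' Train an associative co-occurrence learner
#'
#' Accumulates the word-by-object co-occurrence count matrix over the
#' training phase: every word of a trial co-occurs once with both displayed
#' objects.
#'
#' @param training training-trial data.frame
#'   (\code{\link{assemble_training_trials}}).
#' @param pairs the word-object assignment (defines matrix dimensions).
#' @return integer matrix, rows = word ids, columns = object ids.
#' @export
train_associative <- function(training, pairs) {
  M <- matrix(0L, nrow(pairs), nrow(pairs),
              dimnames = list(pairs$word_id, pairs$object_id))
  if (is.null(training) || !nrow(training)) return(M)
  for (i in seq_len(nrow(training))) {
    tr <- training[i, ]
    for (w in c(tr$first_word, tr$second_word)) {
      M[w, tr$left_object] <- M[w, tr$left_object] + 1L
      M[w, tr$right_object] <- M[w, tr$right_object] + 1L
    }
  }
  M
}

# choice probabilities of the associative learner over the 4 displayed objects
softmax_choice_probs <- function(counts, temperature, lapse_rate) {
  if (temperature == 0) {
    p <- as.numeric(counts == max(counts))
    p <- p / sum(p)
  } else {
    z <- counts / temperature
    z <- z - max(z)
    p <- exp(z) / sum(exp(z))
  }
  (1 - lapse_rate) * p + lapse_rate / length(counts)
}

#' Choose an object on a 4AFC test trial
#'
#' Softmax over the four displayed objects' co-occurrence counts with the
#' probe word, mixed with a uniform lapse component.
#'
#' @param M co-occurrence matrix from \code{\link{train_associative}}.
#' @param trial one row of a test-trial data.frame.
#' @param config a \code{\link{participant_config}}.
#' @return the chosen object id.
#' @export
choose_at_test <- function(M, trial, config) {
  objs <- c(trial$obj_ul, trial$obj_ur, trial$obj_ll, trial$obj_lr)
  counts <- M[trial$probe_word, objs]
  p <- softmax_choice_probs(counts, config$softmax_temperature,
                            config$lapse_rate)
  sample(objs, 1L, prob = p)
}

sim_rts <- function(n, config) {
  rt <- stats::rlnorm(n, config$rt_log_mean, config$rt_log_sd)
  contam <- stats::runif(n) < config$contamination_rate
  rt[contam] <- stats::runif(sum(contam), config$contamination_range[1],
                             config$contamination_range[2])
  list(rt_ms = rt, contaminated = contam)
}

#' Simulate a cohort of participants on a design
#'
#' Runs \code{n_participants} simulated learners through the design's test
#' phase and returns one response record per test trial. Reproducible:
#' identical design, config and seed give identical records. The
#' \code{rt_contaminated} column marks planted far-outlier RTs (ground truth
#' for exclusion-filter checks).
#'
#' @param design a \code{cswl_design}.
#' @param n_participants number of simulated participants (default 30).
#' @param config a \code{\link{participant_config}}.
#' @return data.frame of response records: \code{participant_id, trial_index,
#'   pair_id, set_label, repetition, chosen_object, correct, rt_ms,
#'   rt_contaminated}.
#' @export
simulate_cohort <- function(design, n_participants = 30,
                            config = participant_config()) {
  stopifnot(n_participants >= 1)
  set.seed(config$seed)
  tst <- design$test
  nt <- nrow(tst)
  obj_cols <- c("obj_ul", "obj_ur", "obj_ll", "obj_lr")
  is_plus <- tst$set_label == "PP_plus"
  if (config$learner == "glmm_generative") {
    u_s <- stats::rnorm(nrow(design$pairs), 0, config$tau_stimulus)
    names(u_s) <- design$pairs$pair_id
  }
  if (config$learner == "associative") {
    M <- train_associative(design$training, design$pairs)
  }
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    chosen <- character(nt)
    if (config$learner == "glmm_generative") {
      u_p <- stats::rnorm(1, 0, config$tau_participant)
      eta <- stats::qlogis(0.25) + config$beta0 +
        config$delta_pp_plus * is_plus + u_p + u_s[tst$pair_id]
      correct <- stats::runif(nt) < stats::plogis(eta)
      for (i in seq_len(nt)) {
        objs <- unlist(tst[i, obj_cols], use.names = FALSE)
        chosen[i] <- if (correct[i]) tst$target_object[i] else
          sample(setdiff(objs, tst$target_object[i]), 1L)
      }
    } else if (config$learner == "associative") {
      for (i in seq_len(nt)) chosen[i] <- choose_at_test(M, tst[i, ], config)
    } else {
      for (i in seq_len(nt)) {
        chosen[i] <- sample(unlist(tst[i, obj_cols], use.names = FALSE), 1L)
      }
    }
    rts <- sim_rts(nt, config)
    out[[p]] <- data.frame(
      participant_id = sprintf("p%03d", p), trial_index = tst$index,
      pair_id = tst$pair_id, set_label = tst$set_label,
      repetition = tst$repetition, chosen_object = chosen,
      correct = chosen == tst$target_object, rt_ms = rts$rt_ms,
      rt_contaminated = rts$contaminated, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
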
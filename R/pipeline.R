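default_pipeline_config <- function() {
  list(
    paths = list(lexicon = NULL, inventory = NULL, output_dir = "cswl_out"),
    phonotactics = list(aggregation = "sum"),
    search = list(template = c("C", "V", "C", "V"), k = 6, floor = 0.75,
                  max_shared_biphones = 0, max_initial_repeats = 2,
                  mode = "syllable"),
    design = list(pairs_per_set = 6, exposures_per_pair = 6,
                  test_repetitions = 2, interleave = "max_run", max_run = 2,
                  counterbalance_version = "A"),
    simulation = list(n_participants = 30, learner = "glmm_generative",
                      beta0 = log(7.61), delta_pp_plus = log(1.19),
                      tau_participant = sqrt(2.35), tau_stimulus = sqrt(0.21),
                      softmax_temperature = 1, lapse_rate = 0,
                      rt_log_mean = log(1200), rt_log_sd = 0.35,
                      contamination_rate = 0.02),
    analysis = list(k = 3, scope = "global", n_boot = 2000, bayesian = TRUE,
                    n_chains = 3, n_adapt = 500, n_iter = 10000),
    power = list(d = 4.37, n = 30, alpha = 0.05),
    seed = 1L
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Pipeline configuration
#'
#' Builds a validated configuration for \code{\link{run_stage}} /
#' \code{\link{run_all}}, starting from defaults that mirror the study
#' conditions (6+6 pairs, 36 training / 24 test trials, 30 participants,
#' generative parameters from the fitted full-dataset model) and merging in
#' a YAML or JSON file and/or explicit overrides (file values override
#' defaults; \code{...} overrides the file). When no lexicon path is given
#' the bundled synthetic toy lexicon is used.
#'
#' @param file optional path to a YAML (or JSON) configuration file.
#' @param ... named top-level sections to override, e.g.
#'   \code{simulation = list(n_participants = 10)}.
#' @param seed optional global seed override; per-stage sub-seeds are
#'   derived from it deterministically.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(file = NULL, ..., seed = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(file)) {
    cfg <- merge_config(cfg, yaml::read_yaml(file))
  }
  cfg <- merge_config(cfg, list(...))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  fail <- function(field, why) stop(sprintf("invalid config at %s: %s", field, why))
  if (!cfg$phonotactics$aggregation %in% c("sum", "mean")) {
    fail("phonotactics.aggregation", "must be 'sum' or 'mean'")
  }
  if (!all(cfg$search$template %in% c("C", "V"))) {
    fail("search.template", "symbols must be C or V")
  }
  if (cfg$search$k < 1) fail("search.k", "must be >= 1")
  if (cfg$search$floor <= 0 || cfg$search$floor >= 1) {
    fail("search.floor", "must be in (0, 1)")
  }
  with(cfg$design, {
    if ((pairs_per_set * exposures_per_pair) %% 2L != 0L) {
      fail("design", "pairs_per_set * exposures_per_pair must be even")
    }
  })
  if (cfg$simulation$n_participants < 1) fail("simulation.n_participants", "must be >= 1")
  if (!cfg$simulation$learner %in% c("glmm_generative", "associative", "guesser")) {
    fail("simulation.learner", "unknown learner")
  }
  if (cfg$analysis$k <= 0) fail("analysis.k", "must be > 0")
  if (!cfg$analysis$scope %in% c("global", "per_participant")) {
    fail("analysis.scope", "must be 'global' or 'per_participant'")
  }
  if (cfg$power$n < 2) fail("power.n", "must be >= 2")
  if (cfg$power$alpha <= 0 || cfg$power$alpha >= 1) fail("power.alpha", "must be in (0,1)")
  invisible(cfg)
}

PIPELINE_STAGES <- c("phonotactics", "genwords", "design", "simulate",
                     "analyze", "power")

# deterministic per-stage sub-seed fan-out (kept within 32-bit range)
stage_seed <- function(seed, stage) {
  idx <- match(stage, PIPELINE_STAGES)
  (abs(as.integer(seed)) %% 21000000L) * 100L + idx
}

config_inventory <- function(cfg) {
  if (is.null(cfg$paths$inventory)) toy_inventory() else
    read_inventory(cfg$paths$inventory)
}

config_lexicon <- function(cfg, inventory) {
  if (is.null(cfg$paths$lexicon)) toy_lexicon() else
    read_lexicon(cfg$paths$lexicon, inventory)
}

write_manifest <- function(out_dir, stage, seed, inputs, outputs) {
  man <- list(stage = stage, package = "cswltools",
              version = as.character(utils::packageVersion("cswltools")),
              seed = seed, inputs = inputs,
              outputs = as.list(tools::md5sum(outputs)))
  names(man$outputs) <- basename(outputs)
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}

read_stimuli_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Run one pipeline stage
#'
#' Stages: \code{phonotactics} (biphone table from the lexicon),
#' \code{genwords} (PP+ search and PP- recombination), \code{design}
#' (training/test trial tables and design report), \code{simulate} (cohort
#' response records), \code{analyze} (RT exclusion, full/halved datasets,
#' frequentist and optionally Bayesian chance-offset models, accuracy
#' bootstrap), \code{power} (one-sample t power). Each stage writes its
#' outputs plus a machine-readable manifest (inputs, sub-seed, package
#' version, output checksums) to the configured output directory and reads
#' its upstream inputs from there.
#'
#' @param stage one of the names above.
#' @param config a \code{\link{pipeline_config}}.
#' @return the stage's main result, invisibly; side effect: files under
#'   \code{config$paths$output_dir}.
#' @export
run_stage <- function(stage, config = pipeline_config()) {
  if (!stage %in% PIPELINE_STAGES) {
    stop("unknown stage '", stage, "'; stages: ",
         paste(PIPELINE_STAGES, collapse = ", "))
  }
  out_dir <- config$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sseed <- stage_seed(config$seed, stage)
  need <- function(path, from) {
    if (!file.exists(path)) {
      stop(sprintf("stage '%s' needs missing upstream output %s (run stage '%s' first)",
                   stage, path, from))
    }
    path
  }
  result <- switch(stage,
    phonotactics = {
      inv <- config_inventory(config)
      lex <- config_lexicon(config, inv)
      tab <- biphone_table(lex)
      f <- file.path(out_dir, "biphone_table.tsv")
      write_biphone_table(tab, f)
      write_manifest(out_dir, stage, sseed,
                     list(lexicon = config$paths$lexicon %||% "bundled",
                          entries = nrow(lex)), f)
      message(sprintf("[phonotactics] %d lexicon rows -> %d positional biphones",
                      nrow(lex), nrow(tab$prob)))
      tab
    },
    genwords = {
      need(file.path(out_dir, "biphone_table.tsv"), "phonotactics")
      inv <- config_inventory(config)
      lex <- config_lexicon(config, inv)
      tab <- biphone_table(lex)
      cand <- generate_candidates(tab, inv, lex,
                                  template = config$search$template,
                                  aggregation = config$phonotactics$aggregation)
      plus <- select_top_set(cand, tab, k = config$search$k,
                             constraints = list(
                               max_shared_biphones = config$search$max_shared_biphones,
                               max_initial_repeats = config$search$max_initial_repeats),
                             lexicon = lex)
      minus <- recombine_biphones(plus, tab, inv, lex, k = config$search$k,
                                  floor = config$search$floor,
                                  mode = config$search$mode)
      stim <- do.call(rbind, lapply(list(plus, minus), function(s) {
        data.frame(label = s$label,
                   word_id = vapply(s$words, function(w)
                     paste(w$phonemes, collapse = ""), character(1)),
                   phonemes = vapply(s$words, function(w)
                     paste(w$phonemes, collapse = " "), character(1)),
                   pp = vapply(s$words, function(w) w$pp, numeric(1)),
                   stringsAsFactors = FALSE)
      }))
      f <- file.path(out_dir, "stimuli.tsv")
      utils::write.table(stim, f, sep = "\t", quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
      write_manifest(out_dir, stage, sseed,
                     list(candidates = nrow(cand),
                          mean_pp_plus = plus$mean_pp,
                          mean_pp_minus = minus$mean_pp), f)
      message(sprintf("[genwords] %d candidates -> PP+ mean %.5f, PP- mean %.5f",
                      nrow(cand), plus$mean_pp, minus$mean_pp))
      list(pp_plus = plus, pp_minus = minus)
    },
    design = {
      stim_path <- file.path(out_dir, "stimuli.tsv")
      if (file.exists(stim_path)) {
        stim <- read_stimuli_tsv(stim_path)
        word_ids <- stim$word_id
        set_labels <- ifelse(stim$label == "PP_plus", "PP_plus", "PP_minus")
      } else {
        n <- 2L * config$design$pairs_per_set
        word_ids <- sprintf("w%02d", seq_len(n))
        set_labels <- rep(c("PP_plus", "PP_minus"),
                          each = config$design$pairs_per_set)
      }
      spec <- design_spec(pairs_per_set = config$design$pairs_per_set,
                          exposures_per_pair = config$design$exposures_per_pair,
                          test_repetitions = config$design$test_repetitions,
                          interleave = config$design$interleave,
                          max_run = config$design$max_run,
                          counterbalance_version = config$design$counterbalance_version,
                          seed = sseed)
      des <- generate_design(spec, word_ids = word_ids,
                             set_labels = set_labels,
                             object_ids = sprintf("o%02d", seq_along(word_ids)))
      rep_ <- validate_design(des)
      ftr <- file.path(out_dir, "training_trials.csv")
      fte <- file.path(out_dir, "test_trials.csv")
      fpa <- file.path(out_dir, "pairs.csv")
      frp <- file.path(out_dir, "design_report.json")
      utils::write.csv(des$training, ftr, row.names = FALSE)
      utils::write.csv(rbind(des$test, des$warmup), fte, row.names = FALSE)
      utils::write.csv(des$pairs, fpa, row.names = FALSE)
      jsonlite::write_json(
        list(diag_min = rep_$diag_min, offdiag_max = rep_$offdiag_max,
             cross_set_max = rep_$cross_set_max,
             n_first_referent_left = rep_$n_first_referent_left,
             violations = rep_$violations),
        frp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
      write_manifest(out_dir, stage, sseed,
                     list(n_pairs = nrow(des$pairs)),
                     c(ftr, fte, fpa, frp))
      message(sprintf("[design] %d training + %d test trials (+%d warm-up); %s",
                      nrow(des$training), nrow(des$test), nrow(des$warmup),
                      if (length(rep_$violations)) "VIOLATIONS" else "no violations"))
      des
    },
    simulate = {
      need(file.path(out_dir, "pairs.csv"), "design")
      des <- rebuild_design(config)
      sim <- config$simulation
      pc <- participant_config(learner = sim$learner,
                               softmax_temperature = sim$softmax_temperature,
                               lapse_rate = sim$lapse_rate, beta0 = sim$beta0,
                               delta_pp_plus = sim$delta_pp_plus,
                               tau_participant = sim$tau_participant,
                               tau_stimulus = sim$tau_stimulus,
                               rt_log_mean = sim$rt_log_mean,
                               rt_log_sd = sim$rt_log_sd,
                               contamination_rate = sim$contamination_rate,
                               seed = sseed)
      rec <- simulate_cohort(des, sim$n_participants, pc)
      f <- file.path(out_dir, "responses.csv")
      utils::write.csv(rec, f, row.names = FALSE)
      write_manifest(out_dir, stage, sseed,
                     list(n_participants = sim$n_participants,
                          learner = sim$learner, rows = nrow(rec)), f)
      message(sprintf("[simulate] %d participants x %d test trials -> %d records",
                      sim$n_participants, nrow(des$test), nrow(rec)))
      rec
    },
    analyze = {
      f_in <- need(file.path(out_dir, "responses.csv"), "simulate")
      rec <- utils::read.csv(f_in, stringsAsFactors = FALSE)
      res <- analyze_responses(rec, config, seed = sseed)
      fjs <- file.path(out_dir, "results.json")
      fcsv <- file.path(out_dir, "coefficients.csv")
      jsonlite::write_json(res$json, fjs, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      utils::write.csv(res$coefficients %||% data.frame(), fcsv,
                       row.names = FALSE)
      write_manifest(out_dir, stage, sseed, list(rows_in = nrow(rec)),
                     c(fjs, fcsv))
      message(sprintf("[analyze] full: %d rows (%d excluded); halved: %d rows (%d excluded)",
                      nrow(res$datasets$full$rows), res$datasets$full$n_excluded,
                      nrow(res$datasets$halved$rows), res$datasets$halved$n_excluded))
      res
    },
    power = {
      pw <- power_one_sample_t(config$power$d, config$power$n,
                               config$power$alpha)
      f <- file.path(out_dir, "power.json")
      jsonlite::write_json(list(d = config$power$d, n = config$power$n,
                                alpha = config$power$alpha, power = pw),
                           f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
      write_manifest(out_dir, stage, sseed, config$power, f)
      message(sprintf("[power] d = %.2f, n = %d -> power %.4f",
                      config$power$d, as.integer(config$power$n), pw))
      pw
    })
  invisible(result)
}

# reconstruct the design deterministically from the config (stage sub-seed)
rebuild_design <- function(config) {
  out_dir <- config$paths$output_dir
  stim_path <- file.path(out_dir, "stimuli.tsv")
  sseed <- stage_seed(config$seed, "design")
  if (file.exists(stim_path)) {
    stim <- read_stimuli_tsv(stim_path)
    word_ids <- stim$word_id
    set_labels <- ifelse(stim$label == "PP_plus", "PP_plus", "PP_minus")
  } else {
    n <- 2L * config$design$pairs_per_set
    word_ids <- sprintf("w%02d", seq_len(n))
    set_labels <- rep(c("PP_plus", "PP_minus"),
                      each = config$design$pairs_per_set)
  }
  spec <- design_spec(pairs_per_set = config$design$pairs_per_set,
                      exposures_per_pair = config$design$exposures_per_pair,
                      test_repetitions = config$design$test_repetitions,
                      interleave = config$design$interleave,
                      max_run = config$design$max_run,
                      counterbalance_version = config$design$counterbalance_version,
                      seed = sseed)
  generate_design(spec, word_ids = word_ids, set_labels = set_labels,
                  object_ids = sprintf("o%02d", seq_along(word_ids)))
}

glmm_result_to_list <- function(r) {
  list(method = r$method, fixed = r$fixed, random = r$random,
       sigma2_residual = r$sigma2_residual, icc = r$icc,
       r2_marginal = r$r2_marginal, r2_conditional = r$r2_conditional,
       combined_odds_pp_plus = combine_odds(r$fixed$odds_ratio[1],
                                            r$fixed$odds_ratio[2]),
       converged = r$converged, separation = r$separation, n_obs = r$n_obs)
}

analyze_responses <- function(records, config, seed) {
  ds <- make_datasets(records, k = config$analysis$k,
                      scope = config$analysis$scope)
  few_participants <- length(unique(records$participant_id)) < 2L
  fits <- list(); coefs <- list()
  for (variant in c("full", "halved")) {
    d <- ds[[variant]]
    if (few_participants) {
      fits[[variant]] <- list(
        frequentist = list(skipped = "random effects inestimable with < 2 participants"))
      next
    }
    fr <- fit_glmm_frequentist(d)
    fits[[variant]] <- list(frequentist = glmm_result_to_list(fr))
    coefs[[length(coefs) + 1L]] <- cbind(variant = variant,
                                         method = "frequentist", fr$fixed)
    if (isTRUE(config$analysis$bayesian)) {
      by <- fit_glmm_bayesian(d, n_chains = config$analysis$n_chains,
                              n_adapt = config$analysis$n_adapt,
                              n_iter = config$analysis$n_iter, seed = seed)
      fits[[variant]]$bayesian <- glmm_result_to_list(by)
      coefs[[length(coefs) + 1L]] <- cbind(variant = variant,
                                           method = "bayesian", by$fixed)
    }
  }
  acc <- if (few_participants) NULL else
    lapply(ds, accuracy_summary, n_boot = config$analysis$n_boot, seed = seed)
  list(json = list(accuracy = acc, models = fits,
                   n_excluded = list(full = ds$full$n_excluded,
                                     halved = ds$halved$n_excluded),
                   chance_offset = ds$full$offset),
       coefficients = if (length(coefs)) do.call(rbind, coefs) else NULL,
       datasets = ds, fits = fits)
}

#' Run the full synthetic replication pipeline
#'
#' Executes all stages in order (stimuli, design, cohort simulation,
#' analysis, power) on the configured (by default bundled) lexicon and
#' returns a report with the design summary, per-set accuracies, odds
#' ratios, ICCs and power.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{pipeline_report}; side effect: all stage
#'   outputs, manifests and \code{report.json} under the output directory.
#' @export
run_all <- function(config = pipeline_config()) {
  run_stage("phonotactics", config)
  run_stage("genwords", config)
  des <- run_stage("design", config)
  run_stage("simulate", config)
  res <- run_stage("analyze", config)
  pw <- run_stage("power", config)
  rep_ <- validate_design(des)
  report <- list(
    design = list(n_pairs = nrow(des$pairs),
                  pairs_per_set = des$spec$pairs_per_set,
                  exposures_per_pair = des$spec$exposures_per_pair,
                  test_repetitions = des$spec$test_repetitions,
                  n_training_trials = nrow(des$training),
                  n_test_trials = nrow(des$test),
                  violations = rep_$violations),
    accuracy = res$json$accuracy,
    models = res$json$models,
    power = pw,
    seed = config$seed)
  jsonlite::write_json(report, file.path(config$paths$output_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d pairs, %d training / %d test trials, power %.3f\n",
              x$design$n_pairs, x$design$n_training_trials,
              x$design$n_test_trials, x$power))
  invisible(x)
}
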
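#' Exclude reaction-time outliers
#'
#' Removes trials whose RT lies more than \code{k} standard deviations from
#' the mean, computed in a single pass at the declared scope (globally over
#' all rows, or within each participant). Scopes with fewer than 2 rows have
#' no defined SD: nothing is excluded there and a warning is raised.
#'
#' @param records response-record data.frame with an \code{rt_ms} column.
#' @param k SD multiplier (default 3); \code{Inf} excludes nothing.
#' @param scope \code{"global"} (default) or \code{"per_participant"}.
#' @return list: \code{records} (filtered rows), \code{n_excluded}.
#' @export
exclude_rt_outliers <- function(records, k = 3,
                                scope = c("global", "per_participant")) {
  scope <- match.arg(scope)
  stopifnot(all(records$rt_ms > 0))
  keep_in <- function(rt) {
    if (length(rt) < 2L) {
      warning("fewer than 2 rows in an exclusion scope; SD undefined, nothing excluded")
      return(rep(TRUE, length(rt)))
    }
    s <- stats::sd(rt)
    if (s == 0 || !is.finite(k)) return(rep(TRUE, length(rt)))
    abs(rt - mean(rt)) <= k * s
  }
  keep <- if (scope == "global") keep_in(records$rt_ms) else {
    unsplit(lapply(split(records$rt_ms, records$participant_id), keep_in),
            records$participant_id)
  }
  list(records = records[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Build the full and halved analysis datasets
#'
#' The full dataset keeps both test probes of every pair (up to 24 trials
#' per participant); the halved dataset keeps only each pair's first probe
#' (12 trials), removing within-test learning opportunities. RT exclusion is
#' applied independently to each variant. Both carry the 4AFC chance level
#' and its logit, used as a fixed offset by the models.
#'
#' @param records response records (\code{\link{simulate_cohort}} schema).
#' @param k,scope passed to \code{\link{exclude_rt_outliers}}.
#' @param chance_level 4AFC chance probability (default 0.25).
#' @return list with elements \code{full} and \code{halved}, each of class
#'   \code{analysis_dataset}: \code{variant}, \code{rows}, \code{n_excluded},
#'   \code{chance_level}, \code{offset} (= logit(chance_level)).
#' @export
make_datasets <- function(records, k = 3, scope = "global",
                          chance_level = 0.25) {
  mk <- function(rows, variant) {
    ex <- exclude_rt_outliers(rows, k = k, scope = scope)
    structure(list(variant = variant, rows = ex$records,
                   n_excluded = ex$n_excluded, chance_level = chance_level,
                   offset = stats::qlogis(chance_level)),
              class = "analysis_dataset")
  }
  list(full = mk(records, "full"),
       halved = mk(records[records$repetition == 1L, , drop = FALSE], "halved"))
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat(sprintf("<analysis_dataset> %s: %d rows (%d RT-excluded), chance %.2f (offset %.4f)\n",
              x$variant, nrow(x$rows), x$n_excluded, x$chance_level, x$offset))
  invisible(x)
}

glmm_result <- function(fixed, random, icc, r2, converged, separation, n_obs,
                        method, extra = list()) {
  structure(c(list(fixed = fixed, random = random,
                   sigma2_residual = pi^2 / 3, icc = icc,
                   r2_marginal = r2[1], r2_conditional = r2[2],
                   converged = converged, separation = separation,
                   n_obs = n_obs, method = method), extra),
            class = "glmm_result")
}

#' @export
print.glmm_result <- function(x, ...) {
  cat(sprintf("<glmm_result> %s, %d observations%s%s\n", x$method, x$n_obs,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$separation) " [SEPARATION]" else ""))
  fx <- x$fixed
  for (i in seq_len(nrow(fx))) {
    cat(sprintf("  %-22s OR %6.2f  [%5.2f, %6.2f] (%s)\n", fx$term[i],
                fx$odds_ratio[i], fx$ci_low[i], fx$ci_high[i],
                fx$interval_kind[i]))
  }
  for (i in seq_len(nrow(x$random))) {
    cat(sprintf("  tau00 %-16s %6.3f\n", x$random$group[i], x$random$variance[i]))
  }
  cat(sprintf("  sigma2 %.2f  ICC %.2f  R2 marginal/conditional %.3f/%.3f\n",
              x$sigma2_residual, x$icc, x$r2_marginal, x$r2_conditional))
  invisible(x)
}

prep_model_frame <- function(dataset) {
  d <- dataset$rows
  d$set_label <- factor(d$set_label, levels = c("PP_minus", "PP_plus"))
  d$participant_id <- factor(d$participant_id)
  d$pair_id <- factor(d$pair_id)
  d$.offset <- rep(dataset$offset, nrow(d))
  d
}

#' Fit the chance-offset mixed logistic model (frequentist)
#'
#' Binomial GLMM with logit link for correct/incorrect 4AFC selections:
#' fixed effects are the chance level, entered as a constant offset
#' \code{logit(0.25)} so the intercept directly measures above-chance
#' selection of the reference (PP-) set, and the phonotactic set contrast
#' (PP+ vs PP-); random intercepts for stimuli (pairs) and participants.
#' Estimated by Laplace approximation (\code{lme4::glmer}); intervals are
#' Wald on the log-odds scale, exponentiated to odds ratios. ICC and
#' marginal/conditional R2 are computed on the latent scale with residual
#' variance fixed at \eqn{\pi^2/3}.
#'
#' @param dataset an \code{analysis_dataset}.
#' @param conf_level interval level (default 0.95).
#' @return a \code{glmm_result}; \code{converged} is \code{FALSE} when the
#'   optimizer reports problems, and \code{separation} is \code{TRUE} for
#'   degenerate all-correct/all-incorrect responses (the fit is still
#'   attempted).
#' @export
fit_glmm_frequentist <- function(dataset, conf_level = 0.95) {
  d <- prep_model_frame(dataset)
  if (nlevels(d$participant_id) < 2L || nlevels(d$pair_id) < 2L) {
    stop("need at least 2 participants and 2 stimuli")
  }
  if (nlevels(droplevels(d$set_label)) < 2L) stop("both stimulus sets must be present")
  separation <- length(unique(d$correct)) < 2L
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(correct ~ set_label + (1 | pair_id) + (1 | participant_id),
                  data = d, family = stats::binomial(), offset = d$.offset),
      error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  if (inherits(fit, "error")) {
    fx <- data.frame(term = c("intercept_PPminus", "PPplus"),
                     estimate = NA_real_, odds_ratio = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     interval_kind = "confidence", stringsAsFactors = FALSE)
    rd <- data.frame(group = c("pair_id", "participant_id"),
                     variance = NA_real_, stringsAsFactors = FALSE)
    return(glmm_result(fx, rd, NA_real_, c(NA_real_, NA_real_), FALSE,
                       separation, nrow(d), "frequentist (lme4::glmer)",
                       extra = list(messages = conditionMessage(fit))))
  }
  converged <- length(fit@optinfo$conv$lme4) == 0L &&
    !any(grepl("failed to converge|unable to evaluate", msgs))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  fx <- data.frame(term = c("intercept_PPminus", "PPplus"),
                   estimate = unname(est),
                   odds_ratio = unname(exp(est)),
                   ci_low = unname(exp(est - z * se)),
                   ci_high = unname(exp(est + z * se)),
                   interval_kind = "confidence", stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)
  rd <- data.frame(group = names(vc),
                   variance = vapply(vc, function(v) v[1, 1], numeric(1)),
                   stringsAsFactors = FALSE)
  sigma2 <- pi^2 / 3
  sigma_f2 <- stats::var(as.numeric(stats::model.matrix(fit) %*% est))
  icc <- icc_logistic(rd$variance, sigma2)
  r2 <- r2_nakagawa(sigma_f2, rd$variance, sigma2)
  glmm_result(fx, rd, icc, unlist(r2), converged, separation, nrow(d),
              "frequentist (lme4::glmer)",
              extra = list(messages = msgs, sigma_f2 = sigma_f2, fit = fit))
}

#' Combine intercept and PP+ odds ratios
#'
#' With PP- as the reference level, the intercept OR is the above-chance
#' odds for PP- and the PP+ OR is the multiplicative change from that
#' reference; their product is the above-chance odds of choosing PP+ pairs.
#'
#' @param intercept_or,ppplus_or positive odds ratios.
#' @return the product.
#' @export
combine_odds <- function(intercept_or, ppplus_or) {
  if (any(c(intercept_or, ppplus_or) <= 0)) stop("odds ratios must be positive")
  intercept_or * ppplus_or
}

#' Latent-scale intraclass correlation for logistic mixed models
#'
#' \eqn{ICC = \sum\tau / (\sum\tau + \sigma^2)} with the logistic residual
#' variance \eqn{\sigma^2 = \pi^2/3} on the latent scale.
#'
#' @param tau_components numeric vector of random-effect variances (>= 0).
#' @param sigma2 residual variance (default \eqn{\pi^2/3}).
#' @return the ICC in [0, 1].
#' @export
icc_logistic <- function(tau_components, sigma2 = pi^2 / 3) {
  if (any(tau_components < 0) || sigma2 < 0) stop("variances must be >= 0")
  s <- sum(tau_components)
  if (s + sigma2 == 0) return(0)
  s / (s + sigma2)
}

#' Marginal and conditional R-squared for a GLMM (latent scale)
#'
#' \eqn{R^2_m = \sigma_f^2 / (\sigma_f^2 + \sum\tau + \sigma^2)} and
#' \eqn{R^2_c = (\sigma_f^2 + \sum\tau) / (\sigma_f^2 + \sum\tau + \sigma^2)},
#' where \eqn{\sigma_f^2} is the variance of the fixed-effect linear
#' predictor.
#'
#' @param sigma_f2 fixed-effect predictor variance (>= 0).
#' @param tau_components random-effect variances.
#' @param sigma2 residual variance (default \eqn{\pi^2/3}).
#' @return list \code{marginal}, \code{conditional}.
#' @export
r2_nakagawa <- function(sigma_f2, tau_components, sigma2 = pi^2 / 3) {
  if (sigma_f2 < 0 || any(tau_components < 0) || sigma2 < 0) {
    stop("variance inputs must be >= 0")
  }
  tot <- sigma_f2 + sum(tau_components) + sigma2
  if (tot == 0) return(list(marginal = 0, conditional = 0))
  list(marginal = sigma_f2 / tot,
       conditional = (sigma_f2 + sum(tau_components)) / tot)
}

#' Per-set accuracy with bootstrap confidence intervals
#'
#' Participant-level mean accuracies are resampled over participants with
#' replacement; intervals are percentile bootstrap.
#'
#' @param dataset an \code{analysis_dataset} or a response-record data.frame.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf_level interval level.
#' @param seed integer seed.
#' @return data.frame \code{set_label, mean, ci_low, ci_high, n_participants}.
#' @export
accuracy_summary <- function(dataset, n_boot = 2000, conf_level = 0.95,
                             seed = 1L) {
  rows <- if (inherits(dataset, "analysis_dataset")) dataset$rows else dataset
  if (!nrow(rows)) stop("empty dataset")
  set.seed(seed)
  alpha <- (1 - conf_level) / 2
  out <- lapply(split(rows, rows$set_label), function(d) {
    pm <- tapply(d$correct, d$participant_id, mean)
    pm <- pm[!is.na(pm)]
    if (length(pm) < 2L) stop("need at least 2 participants per set")
    boots <- vapply(seq_len(n_boot),
                    function(i) mean(sample(pm, replace = TRUE)), numeric(1))
    data.frame(set_label = d$set_label[1], mean = mean(pm),
               ci_low = unname(stats::quantile(boots, alpha)),
               ci_high = unname(stats::quantile(boots, 1 - alpha)),
               n_participants = length(pm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Power of a one-sample t-test against chance
#'
#' Exact power via the noncentral t distribution: for effect size d and
#' sample size n, the test statistic is noncentral t with df = n - 1 and
#' noncentrality \eqn{d\sqrt{n}}; power is the probability it exceeds the
#' two-sided critical value.
#'
#' @param d standardized effect size (mean accuracy minus chance, over SD).
#' @param n sample size (>= 2).
#' @param alpha two-sided significance level.
#' @return power in [0, 1].
#' @export
power_one_sample_t <- function(d, n, alpha = 0.05) {
  if (n < 2) stop("n must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df <- n - 1
  ncp <- d * sqrt(n)
  tc <- stats::qt(1 - alpha / 2, df)
  (1 - stats::pt(tc, df, ncp)) + stats::pt(-tc, df, ncp)
}
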
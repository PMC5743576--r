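# Treatment-effect hypothesis tests: mixed models with likelihood-ratio
# tests at alpha = 0.05. Perch height uses a Gaussian LMM; move and attack
# counts use Poisson GLMMs with log bout duration as an exposure offset.
# Plot and block enter as random intercepts; the plot-level presubsidy
# mean of the response is a fixed covariate. Count models additionally
# carry an observation-level random intercept (lognormal-Poisson): bout
# counts are overdispersed relative to Poisson whenever activity varies
# between bouts, and without that term the interaction LRT is grossly
# anticonservative (empirical type-I error several times alpha under the
# generator's null).

response_column <- function(response = c("perch", "moves", "attacks")) {
  response <- match.arg(response)
  switch(response,
         perch = "tw_mean_perch", moves = "n_moves", attacks = "n_attacks")
}

# baseline covariate uses rates for counts so that it is exposure-free
baseline_column <- function(response = c("perch", "moves", "attacks")) {
  switch(match.arg(response),
         perch = "tw_mean_perch", moves = "move_rate", attacks = "attack_rate")
}

new_test_result <- function(term, statistic, df, p_value, model = NULL,
                            alpha = 0.05, extra = list()) {
  structure(c(list(term = term, statistic = unname(statistic),
                   df = unname(df), p_value = unname(p_value),
                   alpha = alpha, model = model), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test for `%s`: chisq = %.3f, df = %d, p = %.4g %s\n",
              x$term, x$statistic, x$df, x$p_value,
              if (x$p_value < x$alpha) sprintf("(significant at alpha = %g)", x$alpha)
              else sprintf("(not significant at alpha = %g)", x$alpha)))
  if (!is.null(x$model)) cat("  model: ", x$model, "\n", sep = "")
  invisible(x)
}

#' Plot-level presubsidy baselines of a response
#'
#' The mean of the chosen response over each plot's presubsidy bouts
#' (`time_since_subsidy_min < 0`), used as a plot-level covariate to
#' absorb pre-existing differences among plots. For the count responses
#' the baseline is the presubsidy rate (count per minute), so it does not
#' depend on bout durations.
#'
#' @param summaries Per-bout summary table from [summarize_bouts()].
#' @param response One of `"perch"`, `"moves"`, `"attacks"`.
#' @return A data.frame with columns `plot_id` and `baseline`.
#' @export
presubsidy_baseline <- function(summaries, response = c("perch", "moves", "attacks")) {
  response <- match.arg(response)
  col <- baseline_column(response)
  pre <- summaries[summaries$time_since_subsidy_min < 0, , drop = FALSE]
  plots <- sort(unique(summaries$plot_id))
  missing_plots <- setdiff(plots, unique(pre$plot_id))
  if (length(missing_plots) > 0)
    stop("no presubsidy bouts for plot(s): ", paste(missing_plots, collapse = ", "))
  means <- tapply(pre[[col]], pre$plot_id, mean)
  data.frame(plot_id = names(means), baseline = as.numeric(means),
             stringsAsFactors = FALSE)
}

# Shared prep: postsubsidy rows, factors, scaled time (hours), centred
# baseline covariate merged by plot.
prep_post_data <- function(summaries, response, baselines) {
  col <- response_column(response)
  d <- summaries[summaries$time_since_subsidy_min >= 0, , drop = FALSE]
  if (nrow(d) == 0) stop("no postsubsidy bouts to analyse")
  if (length(unique(d$treatment)) < 2)
    stop("design error: postsubsidy data must include both arms")
  if (is.null(baselines)) baselines <- presubsidy_baseline(summaries, response)
  d$baseline <- baselines$baseline[match(d$plot_id, baselines$plot_id)]
  if (any(is.na(d$baseline)))
    stop("no presubsidy baseline for plot(s): ",
         paste(unique(d$plot_id[is.na(d$baseline)]), collapse = ", "))
  d$baseline <- d$baseline - mean(d$baseline)
  d$treatment <- factor(d$treatment, levels = c("control", "treatment"))
  d$time_h <- d$time_since_subsidy_min / 60
  d$response <- d[[col]]
  d
}

# Fit full/reduced (g)lmer models by ML and assemble the LRT for the
# dropped term. Singular-fit and convergence chatter is suppressed here;
# genuine failures still error.
lrt_drop_term <- function(full_f, reduced_f, data, family, term, model_desc,
                          extra = list()) {
  fit <- function(f) {
    if (is.null(family))
      lme4::lmer(f, data = data, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))
    else
      # nAGQ = 0 (penalized-likelihood fit): with the observation-level
      # intercept the full Laplace fit is several times slower and gives
      # the same LRT calibration at this design's size
      lme4::glmer(f, data = data, family = family, nAGQ = 0L,
                  control = lme4::glmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))
  }
  full <- suppressMessages(suppressWarnings(fit(full_f)))
  reduced <- suppressMessages(suppressWarnings(fit(reduced_f)))
  an <- suppressMessages(anova(reduced, full))
  stat <- an$Chisq[2]
  df <- an$Df[2]
  p <- an$`Pr(>Chisq)`[2]
  if (!is.finite(stat) || !is.finite(p))
    stop("likelihood-ratio test failed for term `", term, "` (non-finite statistic)")
  new_test_result(term, max(stat, 0), df, p, model = model_desc,
                  extra = c(extra, list(full_fit = full)))
}

#' Test the treatment-by-time-since-subsidy interaction
#'
#' Fits the full mixed model of a response on treatment, time since
#' subsidy and their interaction (fixed effects), the plot-level
#' presubsidy baseline (covariate), and random intercepts for plot and
#' block, to all postsubsidy bouts; then drops the interaction and
#' reports the likelihood-ratio test (df = 1). Perch height uses a
#' Gaussian linear mixed model of the time-weighted mean; move and attack
#' counts use Poisson models with `log(duration_min)` as offset and an
#' observation-level random intercept to absorb the between-bout
#' overdispersion that activity variation produces (without it the LRT is
#' badly anticonservative). Models are fitted by maximum likelihood
#' (lme4).
#'
#' @param summaries Per-bout summary table from [summarize_bouts()].
#' @param response One of `"perch"`, `"moves"`, `"attacks"`.
#' @param baselines Optional data.frame from [presubsidy_baseline()];
#'   computed from `summaries` when `NULL`.
#' @return A `"test_result"` for the interaction term.
#' @export
test_treatment_by_time <- function(summaries,
                                   response = c("perch", "moves", "attacks"),
                                   baselines = NULL) {
  response <- match.arg(response)
  d <- prep_post_data(summaries, response, baselines)
  if (response == "perch") {
    full <- response ~ treatment * time_h + baseline + (1 | plot_id) + (1 | block_id)
    red  <- response ~ treatment + time_h + baseline + (1 | plot_id) + (1 | block_id)
    fam <- NULL
    desc <- "lmer: tw_mean_perch ~ treatment * time + baseline + (1|plot) + (1|block), ML"
  } else {
    full <- response ~ treatment * time_h + baseline +
      offset(log(duration_min)) + (1 | plot_id) + (1 | block_id) + (1 | bout_id)
    red  <- response ~ treatment + time_h + baseline +
      offset(log(duration_min)) + (1 | plot_id) + (1 | block_id) + (1 | bout_id)
    fam <- stats::poisson()
    desc <- paste0("glmer: ", response_column(response),
                   " ~ treatment * time + baseline + offset(log(duration)) + ",
                   "(1|plot) + (1|block) + (1|bout), Poisson")
  }
  lrt_drop_term(full, red, d, fam, "treatment:time_since_subsidy", desc,
                extra = list(response = response))
}

#' Test the perch-height / distance-to-subsidy relationship
#'
#' In subsidized plots after the pulse, fits a linear mixed model of the
#' bout's time-weighted mean perch height on its (dwell-weighted) mean
#' distance to the subsidy, with a random intercept for plot, and reports
#' the likelihood-ratio test for the distance slope (df = 1) together
#' with the slope's sign.
#'
#' @param summaries Per-bout summary table; only treatment-arm
#'   postsubsidy bouts with recorded distances are used.
#' @return A `"test_result"` with elements `slope` (cm perch per cm
#'   distance) and `n` in addition to the test fields.
#' @export
test_perch_vs_distance <- function(summaries) {
  d <- summaries[summaries$treatment == "treatment" &
                   summaries$time_since_subsidy_min >= 0, , drop = FALSE]
  if (nrow(d) == 0) stop("no postsubsidy treatment-arm bouts")
  if (all(is.na(d$mean_distance_cm)))
    stop("no distance-to-seaweed measurements available")
  d <- d[is.na(d$mean_distance_cm) == FALSE, , drop = FALSE]
  if (stats::var(d$mean_distance_cm) == 0)
    stop("degenerate predictor: distance to seaweed is constant")
  d$response <- d$tw_mean_perch
  res <- lrt_drop_term(response ~ mean_distance_cm + (1 | plot_id),
                       response ~ 1 + (1 | plot_id),
                       d, NULL, "distance_to_seaweed",
                       "lmer: tw_mean_perch ~ distance + (1|plot), ML")
  res$slope <- unname(lme4::fixef(res$full_fit)["mean_distance_cm"])
  res$n <- nrow(d)
  res
}

#' Test the treatment-by-stage interaction
#'
#' Fits the postsubsidy response on treatment, stage (small vs large,
#' SVL cutoff 30 mm) and their interaction with random intercepts for
#' plot and block, and reports the likelihood-ratio test for the
#' interaction (df = 1). Time since subsidy is not included: stage models
#' are fitted to the postsubsidy bouts without a time trend, reflecting
#' the limited replication within stage classes such designs afford.
#'
#' @inheritParams test_treatment_by_time
#' @param include_baseline Include the plot-level presubsidy baseline
#'   covariate (default `TRUE`).
#' @return A `"test_result"` for the interaction term.
#' @export
test_stage_interaction <- function(summaries,
                                   response = c("perch", "moves", "attacks"),
                                   baselines = NULL, include_baseline = TRUE) {
  response <- match.arg(response)
  if (!"stage" %in% names(summaries) || all(is.na(summaries$stage)))
    stop("`summaries` must contain stage labels")
  d <- prep_post_data(summaries, response,
                      if (include_baseline) baselines else
                        data.frame(plot_id = unique(summaries$plot_id), baseline = 0))
  d$stage <- factor(d$stage, levels = c("small", "large"))
  if (length(unique(stats::na.omit(d$stage))) < 2)
    stop("design error: both stage classes must be present after the subsidy")
  base_term <- if (include_baseline) "baseline + " else ""
  if (response == "perch") {
    full <- stats::as.formula(paste0(
      "response ~ treatment * stage + ", base_term, "(1 | plot_id) + (1 | block_id)"))
    red <- stats::as.formula(paste0(
      "response ~ treatment + stage + ", base_term, "(1 | plot_id) + (1 | block_id)"))
    fam <- NULL
    desc <- "lmer: tw_mean_perch ~ treatment * stage [+ baseline] + (1|plot) + (1|block), ML"
  } else {
    full <- stats::as.formula(paste0(
      "response ~ treatment * stage + ", base_term,
      "offset(log(duration_min)) + (1 | plot_id) + (1 | block_id) + (1 | bout_id)"))
    red <- stats::as.formula(paste0(
      "response ~ treatment + stage + ", base_term,
      "offset(log(duration_min)) + (1 | plot_id) + (1 | block_id) + (1 | bout_id)"))
    fam <- stats::poisson()
    desc <- paste0("glmer: ", response_column(response),
                   " ~ treatment * stage [+ baseline] + offset(log(duration)), Poisson")
  }
  lrt_drop_term(full, red, d, fam, "treatment:stage", desc,
                extra = list(response = response))
}
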
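#' Run the full identification pipeline over a corpus
#'
#' Orchestrates the end-to-end protocol per participant: build the NARX
#' design matrices, split the signals 6-train/1-test, grid-search the
#' five base learners, tune the rule-based meta-learner, and evaluate
#' one-step and recursive multi-step predictions of the stack and of
#' every base learner on the held-out signal. Data come either from a
#' trial file / data frame or from the synthetic benchmark generator
#' (exactly one source).
#'
#' @param trials data source: a data frame in the trial-signal layout or
#'   a path to a delimited trial file; \code{NULL} to simulate.
#' @param bench a pre-built [synth_benchmark()] corpus (alternative to
#'   \code{trials}).
#' @param n_participants,mspec,sigma synthetic-corpus settings used when
#'   no data source is given.
#' @param spec a [narx_spec()].
#' @param learners a [stack_learners()] roster.
#' @param horizons forecast horizons, a subset of 1..10.
#' @param tuner meta-learner tuner: \code{"jade"}, \code{"de"} or
#'   \code{"grid"}.
#' @param seed global seed; fanned out deterministically to
#'   per-participant streams.
#' @param out optional output directory: metric, prediction and tuned-
#'   hyperparameter tables are written there as delimited text with a
#'   small run manifest.
#' @param keep_fits keep the fitted \code{"jade_stack"} objects in the
#'   report (memory-heavy).
#' @param verbose print per-participant progress lines.
#' @param ... further arguments to [jade_stack()].
#' @return list of class \code{"jadestack_report"}: \code{metrics}
#'   (participant x model x horizon VAF/RMSE records), \code{summary}
#'   (Average/Std rows), \code{predictions}, \code{tuned} (per-participant
#'   tuned hyperparameters), \code{whiteness} (one-step residual
#'   whiteness per participant), \code{oracle} (achievable VAF, synthetic
#'   corpora only), \code{config}.
#' @export
run_pipeline <- function(trials = NULL, bench = NULL, n_participants = 2L,
                         mspec = multisine_spec(), sigma = 0.1,
                         spec = narx_spec(), learners = stack_learners(),
                         horizons = c(1L, 3L),
                         tuner = c("jade", "de", "grid"), seed = 1L,
                         out = NULL, keep_fits = FALSE, verbose = FALSE,
                         ...) {
  tuner <- match.arg(tuner)
  horizons <- as.integer(horizons)
  if (length(horizons) == 0L || any(horizons < 1L | horizons > 10L))
    stop("horizons must be a non-empty subset of 1..10")
  if (!is.null(trials) && !is.null(bench))
    stop("give exactly one data source (trials or bench)")
  oracle <- NULL
  if (is.null(trials)) {
    if (is.null(bench))
      bench <- synth_benchmark(n_participants, mspec, sigma = sigma,
                               seed = seed)
    trials <- bench$trials
    oracle <- bench$oracle
  } else if (is.character(trials)) {
    trials <- read_trials(trials)
  }

  stack_label <- c(jade = "JADE-STACK", de = "DE-STACK",
                   grid = "GRID-STACK")[[tuner]]
  participants <- unique(trials$participant)
  metrics <- list()
  preds <- list()
  tuned <- list()
  white <- list()
  fits <- list()
  for (i in seq_along(participants)) {
    p <- participants[i]
    sub <- trials[trials$participant == p, ]
    p_seed <- (seed + 7919L * i) %% .Machine$integer.max
    fit <- jade_stack(sub, spec = spec, learners = learners, tuner = tuner,
                      seed = p_seed, ...)
    if (verbose)
      message(sprintf("participant %s: committees=%d neighbors=%d cv_vaf=%.2f",
                      p, fit$tuning$committees, fit$tuning$neighbors,
                      fit$tuning$cv_vaf))
    test <- fit$test_trial
    test_design <- narx_design(test$u, test$y, spec)
    x_test <- as.matrix(test_design[, narx_columns(spec)])

    for (h in horizons) {
      pr <- predict(fit, horizon = h)
      pr$model <- stack_label
      preds[[length(preds) + 1L]] <- pr
      metrics[[length(metrics) + 1L]] <- data.frame(
        participant = p, model = stack_label, horizon = h,
        vaf = vaf(pr$y, pr$yhat), rmse = rmse(pr$y, pr$yhat))
      if (h == 1L)
        white[[length(white) + 1L]] <- data.frame(
          participant = p,
          K = residual_whiteness(pr$residual)$statistic,
          p.value = residual_whiteness(pr$residual)$p.value)
      for (nm in names(fit$layer0)) {
        l <- fit$layer0[[nm]]
        fn <- function(x) l$spec$predict(l$model, x)
        rf <- recursive_forecast(fn, test$u, test$y, spec, h)
        metrics[[length(metrics) + 1L]] <- data.frame(
          participant = p, model = nm, horizon = h,
          vaf = vaf(rf$y, rf$yhat), rmse = rmse(rf$y, rf$yhat))
      }
    }
    tuned[[length(tuned) + 1L]] <- data.frame(
      participant = p, committees = fit$tuning$committees,
      neighbors = fit$tuning$neighbors, cv_vaf = fit$tuning$cv_vaf)
    if (keep_fits) fits[[as.character(p)]] <- fit
  }

  metrics <- do.call(rbind, metrics)
  report <- structure(list(
    metrics = metrics,
    summary = summarize_metrics(metrics),
    predictions = do.call(rbind, preds),
    tuned = do.call(rbind, tuned),
    whiteness = do.call(rbind, white),
    oracle = oracle,
    fits = if (keep_fits) fits else NULL,
    config = list(seed = seed, horizons = horizons, tuner = tuner,
                  spec = unclass(spec), n_participants = length(participants))),
    class = "jadestack_report")
  if (!is.null(out)) write_report(report, out)
  report
}

#' Rank-based statistical comparison of the models in a report
#'
#' Per horizon: a Friedman test over the per-participant VAF of all
#' evaluated models, followed by the Nemenyi critical-difference post hoc
#' when the omnibus test rejects at level \code{alpha}.
#'
#' @param report a \code{"jadestack_report"}.
#' @param alpha significance level.
#' @param metric metric column to compare (\code{"vaf"} or
#'   \code{"rmse"}).
#' @return named list (one element per horizon) of lists with
#'   \code{friedman} and, when significant, \code{nemenyi}.
#' @export
compare_models <- function(report, alpha = 0.05, metric = "vaf") {
  m <- report$metrics
  out <- list()
  for (h in sort(unique(m$horizon))) {
    sub <- m[m$horizon == h, ]
    wide <- tapply(sub[[metric]], list(sub$participant, sub$model), mean)
    if (ncol(wide) < 3L) stop("need at least 3 models to compare")
    if (nrow(wide) < 2L) stop("need at least 2 participants to compare")
    fr <- friedman_test(wide,
                        better = if (metric == "rmse") "lower" else "higher")
    res <- list(friedman = fr)
    if (fr$p.value < alpha) res$nemenyi <- nemenyi_cd(fr, alpha = alpha)
    out[[as.character(h)]] <- res
  }
  out
}

write_report <- function(report, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(out, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$predictions, file.path(out, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$tuned, file.path(out, "tuned.csv"),
                   row.names = FALSE)
  cfg <- report$config
  lines <- c(sprintf("seed: %d", cfg$seed),
             sprintf("tuner: %s", cfg$tuner),
             sprintf("horizons: %s", paste(cfg$horizons, collapse = ",")),
             sprintf("participants: %d", cfg$n_participants),
             sprintf("ny: %d", cfg$spec$ny), sprintf("nu: %d", cfg$spec$nu),
             sprintf("window: %d", cfg$spec$window))
  writeLines(lines, file.path(out, "manifest.txt"))
  invisible(out)
}

#' @export
print.jadestack_report <- function(x, ...) {
  cat(sprintf("identification report: %d participant(s), tuner %s, horizons %s\n",
              x$config$n_participants, x$config$tuner,
              paste(x$config$horizons, collapse = ", ")))
  s <- x$summary
  s[-(1:2)] <- lapply(s[-(1:2)], round, 3)
  print(s, row.names = FALSE)
  invisible(x)
}
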
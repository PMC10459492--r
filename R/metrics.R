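#' Variance accounted for (VAF)
#'
#' \code{100 * (1 - var(y - yhat) / var(y))}, using the sample variance
#' (divisor n-1) in both terms. 100 means a perfect explanation of the
#' output variability, 0 is no better than the output mean, and negative
#' values are possible. Because both terms are variances the score ignores
#' a constant offset in the predictions.
#'
#' @param y observed output.
#' @param yhat predicted output (same length, >= 2).
#' @return VAF in percent.
#' @export
vaf <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2L) stop("need at least 2 observations")
  vy <- stats::var(y)
  if (vy == 0) stop("VAF undefined: var(y) is zero")
  100 * (1 - stats::var(y - yhat) / vy)
}

#' Root-mean-squared error
#'
#' @inheritParams vaf
#' @return \code{sqrt(mean((y - yhat)^2))}.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  sqrt(mean((y - yhat)^2))
}

#' Column summaries of a metrics table
#'
#' Aggregates per-participant records into the Average and Std rows of a
#' results table: arithmetic mean and \emph{population} standard deviation
#' (divisor n), the convention the reference result tables follow.
#'
#' @param table data frame with columns \code{participant}, \code{model},
#'   \code{horizon} and one or more metric columns (e.g. \code{vaf},
#'   \code{rmse}).
#' @param metrics metric column names to summarise.
#' @return data frame with one row per (model, horizon) and columns
#'   \code{<metric>_mean}, \code{<metric>_std}.
#' @export
summarize_metrics <- function(table, metrics = c("vaf", "rmse")) {
  metrics <- intersect(metrics, names(table))
  groups <- unique(table[c("model", "horizon")])
  out <- groups[order(groups$horizon, groups$model), , drop = FALSE]
  rownames(out) <- NULL
  for (m in metrics) {
    out[[paste0(m, "_mean")]] <- NA_real_
    out[[paste0(m, "_std")]] <- NA_real_
  }
  for (i in seq_len(nrow(out))) {
    rows <- table$model == out$model[i] & table$horizon == out$horizon[i]
    for (m in metrics) {
      v <- table[[m]][rows]
      v <- v[!is.na(v)]
      if (length(v) > 0L) {
        out[[paste0(m, "_mean")]][i] <- mean(v)
        out[[paste0(m, "_std")]][i] <- sd_pop(v)
      }
    }
  }
  out
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Relative improvement of one mean score over another
#'
#' \code{100 * (a - b) / b}: the percent improvement of score \code{a}
#' over baseline \code{b}.
#'
#' @param a,b scalar mean scores; \code{b} must be non-zero.
#' @return percent improvement.
#' @export
relative_improvement <- function(a, b) {
  if (b == 0) stop("zero baseline")
  100 * (a - b) / b
}

#' Friedman rank test for k related models over n blocks
#'
#' Rank-based omnibus test for differences among \code{k >= 3} treatments
#' (models) measured on the same \code{n} blocks (participants). Within
#' each block the models are ranked and the statistic
#' \deqn{FD = \frac{12 n}{k (k+1)} \left[\sum_j \bar R_j^2 -
#'   \frac{k (k+1)^2}{4}\right]}
#' is referred to a chi-squared distribution with k-1 degrees of freedom.
#'
#' @param values n x k numeric matrix: blocks in rows, models in columns.
#' @param better \code{"higher"} if larger values are better (ranked
#'   first), \code{"lower"} otherwise. The statistic itself is direction
#'   invariant; the orientation only affects the reported mean ranks.
#' @param ties \code{"average"} (midranks, the standard convention) or
#'   \code{"first"} (sequential within-row tie-breaking by column order,
#'   reproducing a ranking of values that were rounded into ties).
#' @return list of class \code{"friedman_test"}: \code{statistic},
#'   \code{df}, \code{p.value}, \code{ranks} (n x k, 1 = best),
#'   \code{mean_ranks}, \code{n}, \code{k}.
#' @export
friedman_test <- function(values, better = c("higher", "lower"),
                          ties = c("average", "first")) {
  better <- match.arg(better)
  ties <- match.arg(ties)
  values <- as.matrix(values)
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2L) stop("need at least 2 blocks")
  if (k < 3L) stop("the Friedman test needs more than two models")
  score <- if (better == "higher") values else -values
  # rank k = best; converted below so that rank 1 = best
  R <- t(apply(score, 1L, rank, ties.method = ties))
  Rbar <- colMeans(R)
  FD <- 12 * n / (k * (k + 1)) * (sum(Rbar^2) - k * (k + 1)^2 / 4)
  ranks_best1 <- (k + 1) - R
  mr <- colMeans(ranks_best1)
  names(mr) <- colnames(values)
  structure(list(statistic = FD, df = k - 1L,
                 p.value = stats::pchisq(FD, k - 1L, lower.tail = FALSE),
                 ranks = ranks_best1, mean_ranks = mr, n = n, k = k),
            class = "friedman_test")
}

#' @export
print.friedman_test <- function(x, ...) {
  cat(sprintf("Friedman test: FD = %.4f, df = %d, p = %.4g (n = %d, k = %d)\n",
              x$statistic, x$df, x$p.value, x$n, x$k))
  invisible(x)
}

#' Nemenyi critical difference and pairwise comparisons
#'
#' Post hoc for a rejected Friedman test: two models differ significantly
#' when their mean ranks differ by more than
#' \deqn{CD = \frac{q_{\infty,k,\alpha}}{\sqrt 2}
#'   \sqrt{\frac{k (k+1)}{6 n}},}
#' where \eqn{q} is the studentized range quantile with infinite degrees
#' of freedom (obtained from \code{qtukey}).
#'
#' @param fr a \code{"friedman_test"} result, or \code{NULL} when only the
#'   critical difference for given \code{k} and \code{n} is wanted.
#' @param k,n number of models and blocks (taken from \code{fr} if given).
#' @param alpha significance level in (0, 1).
#' @return list of class \code{"nemenyi_test"}: \code{cd}, \code{q},
#'   \code{alpha}, and — when \code{fr} is supplied — \code{mean_ranks}
#'   and a logical pairwise \code{significant} matrix.
#' @export
nemenyi_cd <- function(fr = NULL, k = fr$k, n = fr$n, alpha = 0.05) {
  if (is.null(k) || is.null(n)) stop("supply a friedman_test result or k and n")
  if (k < 2L || n < 1L) stop("need k >= 2 and n >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  q <- stats::qtukey(1 - alpha, nmeans = k, df = Inf)
  cd <- q / sqrt(2) * sqrt(k * (k + 1) / (6 * n))
  out <- list(cd = cd, q = q, alpha = alpha, k = k, n = n)
  if (!is.null(fr)) {
    mr <- fr$mean_ranks
    sig <- abs(outer(mr, mr, `-`)) > cd
    diag(sig) <- FALSE
    out$mean_ranks <- mr
    out$significant <- sig
  }
  structure(out, class = "nemenyi_test")
}

#' @export
print.nemenyi_test <- function(x, ...) {
  cat(sprintf("Nemenyi post hoc: CD = %.4f (k = %d, n = %d, alpha = %g)\n",
              x$cd, x$k, x$n, x$alpha))
  if (!is.null(x$mean_ranks)) {
    cat("mean ranks (1 = best):\n")
    print(round(sort(x$mean_ranks), 3))
  }
  invisible(x)
}

#' Residual whiteness check
#'
#' One-sample Kolmogorov-Smirnov test of the standardised residuals
#' against the standard normal distribution; a large p-value is consistent
#' with white (Gaussian) residual noise.
#'
#' @param residuals numeric vector, length >= 10.
#' @return list with \code{statistic} (K) and \code{p.value}.
#' @export
residual_whiteness <- function(residuals) {
  if (length(residuals) < 10L) stop("need at least 10 residuals")
  s <- stats::sd(residuals)
  if (s == 0) stop("degenerate residuals: zero variance")
  z <- (residuals - mean(residuals)) / s
  kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}
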
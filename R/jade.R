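#' Adaptive differential evolution (JADE) over a box-bounded continuous space
#'
#' Minimises (or maximises) an objective with the self-adaptive
#' "DE/current-to-pbest/1" differential-evolution strategy: the mutation
#' factor F of every individual is drawn from a Cauchy distribution whose
#' location \code{mu_F} adapts via the Lehmer mean of the generation's
#' successful F values, the crossover probability CR from a normal
#' distribution whose mean \code{mu_CR} adapts via the arithmetic mean of
#' successful CR values, and an optional external archive of replaced
#' parents widens the mutation pool to counteract greediness.
#'
#' Dimensions flagged in \code{integer} are rounded half-away-from-zero to
#' the nearest integer (then clamped into the box) before every objective
#' evaluation, so the search itself stays continuous while the objective
#' only ever sees feasible integer settings. Non-finite objective values are
#' treated as worst-possible fitness rather than raising, so a stochastic
#' objective cannot abort a run.
#'
#' @param objective function of a numeric vector returning a scalar.
#' @param lower,upper numeric vectors of equal length: the search box.
#' @param np population size (>= 4).
#' @param generations number of generations after the initial evaluation.
#' @param c adaptation rate of \code{mu_F}/\code{mu_CR} in (0,1); 0 freezes
#'   both at their initial value 0.5.
#' @param p fraction of the population regarded as "pbest" (top candidates
#'   eligible to lead the mutation), in (0,1].
#' @param maximize if \code{TRUE} the objective is maximised.
#' @param integer logical vector marking dimensions that are rounded at
#'   evaluation time; recycled defaults to all-continuous.
#' @param use_archive keep an external archive of replaced parents
#'   (size-capped at \code{np}) and sample the second difference vector from
#'   population-plus-archive.
#' @param seed optional integer seed; identical seeds give identical runs.
#'
#' @return An object of class \code{"jade_opt"}: a list with elements
#'   \code{par} (best position, integer dimensions decoded), \code{value}
#'   (its objective value on the user's scale), \code{history} (data frame
#'   with one row per generation: best-so-far value, \code{mu_F},
#'   \code{mu_CR}, archive size), \code{evaluations}, \code{maximize},
#'   and \code{method}.
#'
#' @examples
#' sphere <- function(x) sum(x^2)
#' fit <- jade(sphere, lower = rep(-5, 2), upper = rep(5, 2),
#'             np = 20, generations = 50, seed = 1)
#' fit$value
#' @seealso [de_classic()] for the fixed-parameter rand/1/bin baseline.
#' @export
jade <- function(objective, lower, upper, np = 30L, generations = 100L,
                 c = 0.1, p = 0.05, maximize = FALSE, integer = NULL,
                 use_archive = TRUE, seed = NULL) {
  d <- length(lower)
  if (d < 1L || length(upper) != d || any(!(lower < upper)))
    stop("invalid bounds: need lower[j] < upper[j] for every dimension")
  np <- as.integer(np)
  if (np < 4L) stop("population size must be at least 4")
  if (c < 0 || c > 1) stop("'c' must lie in [0,1]")
  if (p <= 0 || p > 1) stop("'p' must lie in (0,1]")
  if (is.null(integer)) integer <- rep(FALSE, d)
  if (!is.null(seed)) set.seed(seed)

  sgn <- if (maximize) -1 else 1
  evals <- 0L
  fwrap <- function(x) {
    v <- objective(decode_integer(x, integer, lower, upper))
    evals <<- evals + 1L
    if (!is.finite(v)) Inf else sgn * v
  }

  pop <- init_population(lower, upper, np)
  fit <- apply(pop, 1L, fwrap)
  mu_F <- 0.5
  mu_CR <- 0.5
  archive <- matrix(numeric(0), nrow = 0L, ncol = d)

  hist_best <- numeric(generations + 1L)
  hist_muF <- numeric(generations + 1L)
  hist_muCR <- numeric(generations + 1L)
  hist_arch <- integer(generations + 1L)
  hist_best[1L] <- min(fit)
  hist_muF[1L] <- mu_F
  hist_muCR[1L] <- mu_CR

  n_top <- max(1L, ceiling(p * np))
  for (g in seq_len(generations)) {
    S_F <- numeric(0)
    S_CR <- numeric(0)
    top <- order(fit)[seq_len(n_top)]
    for (i in seq_len(np)) {
      Fi <- jade_sample_F(mu_F)
      CRi <- jade_sample_CR(mu_CR)
      pb <- top[sample.int(n_top, 1L)]
      r1_pool <- seq_len(np)[-i]
      r1 <- r1_pool[sample.int(np - 1L, 1L)]
      n_union <- np + nrow(archive)
      r2_pool <- setdiff(seq_len(n_union), c(i, r1))
      r2 <- r2_pool[sample.int(length(r2_pool), 1L)]
      xr2 <- if (r2 <= np) pop[r2, ] else archive[r2 - np, ]
      v <- pbest_mutant(pop[i, ], pop[pb, ], pop[r1, ], xr2, Fi)
      v <- midpoint_repair(v, pop[i, ], lower, upper)
      u <- binomial_crossover(pop[i, ], v, CRi)
      fu <- fwrap(u)
      if (fu < fit[i]) {
        if (use_archive) archive <- rbind(archive, pop[i, , drop = FALSE])
        S_F <- c(S_F, Fi)
        S_CR <- c(S_CR, CRi)
        pop[i, ] <- u
        fit[i] <- fu
      }
    }
    archive <- trim_archive(archive, np)
    mu_F <- update_mu_lehmer(mu_F, S_F, c)
    mu_CR <- update_mu_arith(mu_CR, S_CR, c)
    hist_best[g + 1L] <- min(fit, hist_best[g])
    hist_muF[g + 1L] <- mu_F
    hist_muCR[g + 1L] <- mu_CR
    hist_arch[g + 1L] <- nrow(archive)
  }

  b <- which.min(fit)
  structure(list(
    par = decode_integer(pop[b, ], integer, lower, upper),
    value = sgn * fit[b],
    history = data.frame(generation = 0:generations,
                         best = sgn * hist_best,
                         mu_F = hist_muF, mu_CR = hist_muCR,
                         archive_size = hist_arch),
    evaluations = evals, maximize = maximize, method = "jade",
    lower = lower, upper = upper, integer = integer),
    class = "jade_opt")
}

#' Classic differential evolution (rand/1/bin) with fixed F and CR
#'
#' Fixed-parameter baseline sharing the evaluation, bound-repair and
#' selection machinery of [jade()]: mutation \code{x_r1 + F (x_r2 - x_r3)},
#' binomial crossover at constant \code{CR}, strictly-better replacement.
#' Default settings follow the reference tuning protocol (population 100,
#' crossover ratio 0.5, mutation factor 0.2).
#'
#' @inheritParams jade
#' @param F mutation factor.
#' @param CR crossover probability.
#' @return A \code{"jade_opt"} object (see [jade()]) with
#'   \code{method = "de"}; its history carries constant \code{mu_F = F} and
#'   \code{mu_CR = CR} columns and a zero archive.
#' @export
de_classic <- function(objective, lower, upper, np = 100L, generations = 100L,
                       F = 0.2, CR = 0.5, maximize = FALSE, integer = NULL,
                       seed = NULL) {
  d <- length(lower)
  if (d < 1L || length(upper) != d || any(!(lower < upper)))
    stop("invalid bounds: need lower[j] < upper[j] for every dimension")
  np <- as.integer(np)
  if (np < 4L) stop("population size must be at least 4")
  if (is.null(integer)) integer <- rep(FALSE, d)
  if (!is.null(seed)) set.seed(seed)

  sgn <- if (maximize) -1 else 1
  evals <- 0L
  fwrap <- function(x) {
    v <- objective(decode_integer(x, integer, lower, upper))
    evals <<- evals + 1L
    if (!is.finite(v)) Inf else sgn * v
  }

  pop <- init_population(lower, upper, np)
  fit <- apply(pop, 1L, fwrap)
  hist_best <- numeric(generations + 1L)
  hist_best[1L] <- min(fit)

  for (g in seq_len(generations)) {
    for (i in seq_len(np)) {
      pool <- seq_len(np)[-i]
      r <- pool[sample.int(np - 1L, 3L)]
      v <- pop[r[1L], ] + F * (pop[r[2L], ] - pop[r[3L], ])
      v <- midpoint_repair(v, pop[i, ], lower, upper)
      u <- binomial_crossover(pop[i, ], v, CR)
      fu <- fwrap(u)
      if (fu < fit[i]) {
        pop[i, ] <- u
        fit[i] <- fu
      }
    }
    hist_best[g + 1L] <- min(fit, hist_best[g])
  }

  b <- which.min(fit)
  structure(list(
    par = decode_integer(pop[b, ], integer, lower, upper),
    value = sgn * fit[b],
    history = data.frame(generation = 0:generations,
                         best = sgn * hist_best,
                         mu_F = F, mu_CR = CR, archive_size = 0L),
    evaluations = evals, maximize = maximize, method = "de",
    lower = lower, upper = upper, integer = integer),
    class = "jade_opt")
}

#' @export
print.jade_opt <- function(x, ...) {
  cat(sprintf("%s optimisation (%s), %d evaluations\n",
              if (x$method == "jade") "JADE" else "Classic DE",
              if (x$maximize) "maximising" else "minimising",
              x$evaluations))
  cat("best value:", format(x$value, digits = 6), "\n")
  cat("best position:", paste(format(x$par, digits = 5), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.jade_opt <- function(x, ...) {
  plot(x$history$generation, x$history$best, type = "s",
       xlab = "generation", ylab = "best objective", ...)
  invisible(x)
}

## --- internal evolutionary primitives ------------------------------------

# Uniform initialisation x = LB + r (UB - LB).
init_population <- function(lower, upper, np) {
  d <- length(lower)
  r <- matrix(stats::runif(np * d), nrow = np)
  sweep(r, 2L, upper - lower, `*`) + matrix(lower, np, d, byrow = TRUE)
}

# F ~ Cauchy(mu_F, 0.1), resampled while non-positive, truncated to 1.
# `draws` injects a scripted sequence (testing); exhausting it errors.
jade_sample_F <- function(mu_F, draws = NULL) {
  if (is.null(draws)) {
    repeat {
      f <- stats::rcauchy(1L, location = mu_F, scale = 0.1)
      if (f > 0) return(min(f, 1))
    }
  }
  for (f in draws) if (f > 0) return(min(f, 1))
  stop("scripted draws exhausted without a positive value")
}

# CR ~ Normal(mu_CR, 0.1) clipped into [0,1].
jade_sample_CR <- function(mu_CR, draw = NULL) {
  if (is.null(draw)) draw <- stats::rnorm(1L, mean = mu_CR, sd = 0.1)
  min(max(draw, 0), 1)
}

# v = x_i + F (x_pbest - x_i) + F (x_r1 - x_r2~)
pbest_mutant <- function(xi, xpbest, xr1, xr2, F) {
  xi + F * (xpbest - xi) + F * (xr1 - xr2)
}

# Midpoint reflection toward the violated bound: keeps the mutant strictly
# inside and preserves diversity relative to clipping.
midpoint_repair <- function(v, xi, lower, upper) {
  lo <- v < lower
  hi <- v > upper
  v[lo] <- (lower[lo] + xi[lo]) / 2
  v[hi] <- (upper[hi] + xi[hi]) / 2
  v
}

# Binomial crossover; j_rand forces at least one mutant coordinate.
# `u` injects scripted uniforms (testing).
binomial_crossover <- function(target, mutant, CR, jrand = NULL, u = NULL) {
  d <- length(target)
  if (is.null(jrand)) jrand <- sample.int(d, 1L)
  if (is.null(u)) u <- stats::runif(d)
  take <- u <= CR
  take[jrand] <- TRUE
  ifelse(take, mutant, target)
}

lehmer_mean <- function(s) sum(s^2) / sum(s)

update_mu_lehmer <- function(mu, S, c) {
  if (length(S) == 0L) return(mu)
  min(max((1 - c) * mu + c * lehmer_mean(S), 0), 1)
}

update_mu_arith <- function(mu, S, c) {
  if (length(S) == 0L) return(mu)
  min(max((1 - c) * mu + c * mean(S), 0), 1)
}

# Cap the archive at np by discarding uniformly-random members.
trim_archive <- function(archive, np) {
  n <- nrow(archive)
  if (n <= np) return(archive)
  archive[sort(sample.int(n, np)), , drop = FALSE]
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Round integer-flagged dimensions half-away-from-zero, clamp into bounds.
decode_integer <- function(x, integer, lower, upper) {
  if (any(integer)) {
    x[integer] <- pmin(pmax(round_half_away(x[integer]), lower[integer]),
                       upper[integer])
  }
  x
}
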
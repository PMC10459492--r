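#' Lag/feature specification for the NARX design matrix
#'
#' Fixes the regressor structure used throughout the package: \code{ny}
#' lagged outputs, \code{nu} lagged inputs, and six engineered features of
#' the once-lagged input u(t-1) — rolling mean, standard deviation and
#' skewness over a causal window, the first difference u(t-1) - u(t-2), the
#' cube, and a signed logarithm. The first \code{max(ny, nu, window)} rows
#' of every signal are dropped as burn-in so that every regressor is fully
#' observed.
#'
#' @param ny output lag depth (>= 1).
#' @param nu input lag depth (>= 1).
#' @param window causal rolling-window length on u(t-1) (>= 2).
#' @return A list of class \code{"narx_spec"}.
#' @export
narx_spec <- function(ny = 5L, nu = 3L, window = 3L) {
  ny <- as.integer(ny); nu <- as.integer(nu); window <- as.integer(window)
  if (ny < 1L || nu < 1L || window < 2L)
    stop("need ny >= 1, nu >= 1, window >= 2")
  structure(list(ny = ny, nu = nu, window = window,
                 burnin = max(ny, nu, window)),
            class = "narx_spec")
}

#' Signed logarithm
#'
#' \code{sign(x) * log(1 + |x|)}: a total, odd, monotone logarithmic
#' transform usable on signals that cross zero (a plain logarithm is
#' undefined there).
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
signed_log <- function(x) sign(x) * log1p(abs(x))

# Moment-coefficient skewness g1 = m3 / m2^(3/2) over a window; 0 at zero
# variance by convention.
rolling_skewness <- function(values) {
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) return(0)
  mean((values - m)^3) / m2^1.5
}

#' Build the NARX design matrix for one signal
#'
#' Converts a single input/output record into the lagged regressor matrix:
#' row for target time t (1-based) references only samples at times <= t-1,
#' and the first \code{burnin = max(ny, nu, window)} targets are dropped.
#' Columns are \code{y_lag1..y_lag{ny}}, \code{u_lag1..u_lag{nu}},
#' \code{u_mean_w}, \code{u_std_w} (divisor w-1), \code{u_skew_w} (moment
#' coefficient, 0 at zero variance), \code{u_diff12}, \code{u_cube},
#' \code{u_slog}. The rolling window spans u(t-window .. t-1).
#'
#' @param u,y numeric vectors of equal length (input and output signal).
#' @param spec a [narx_spec()].
#' @param participant,signal_id provenance identifiers carried per row.
#' @return A data frame with provenance columns \code{participant},
#'   \code{signal_id}, \code{t} (1-based target time), the target \code{y},
#'   and the regressor columns.
#' @export
narx_design <- function(u, y, spec = narx_spec(), participant = NA,
                        signal_id = NA) {
  if (length(u) != length(y)) stop("u and y must have equal length")
  if (!all(is.finite(u)) || !all(is.finite(y)))
    stop("signals must be finite")
  n <- length(y)
  b <- spec$burnin
  if (n <= b) stop("trial too short: need more than ", b, " samples")
  tt <- (b + 1L):n

  out <- data.frame(participant = participant, signal_id = signal_id, t = tt)
  for (j in seq_len(spec$ny)) out[[paste0("y_lag", j)]] <- y[tt - j]
  for (j in seq_len(spec$nu)) out[[paste0("u_lag", j)]] <- u[tt - j]

  w <- spec$window
  win <- vapply(tt, function(t) {
    v <- u[(t - w):(t - 1L)]
    c(mean(v), stats::sd(v), rolling_skewness(v))
  }, numeric(3L))
  out$u_mean_w <- win[1L, ]
  out$u_std_w <- win[2L, ]
  out$u_skew_w <- win[3L, ]
  out$u_diff12 <- u[tt - 1L] - u[tt - 2L]
  out$u_cube <- u[tt - 1L]^3
  out$u_slog <- signed_log(u[tt - 1L])
  out$y <- y[tt]
  out
}

# Regressor column names for a spec (order matches narx_design).
narx_columns <- function(spec) {
  c(paste0("y_lag", seq_len(spec$ny)), paste0("u_lag", seq_len(spec$nu)),
    "u_mean_w", "u_std_w", "u_skew_w", "u_diff12", "u_cube", "u_slog")
}

# Stack per-signal design matrices for a set of trials (lags never cross
# signal boundaries).
build_designs <- function(trials, spec = narx_spec()) {
  parts <- split(trials, list(trials$participant, trials$signal_id),
                 drop = TRUE)
  out <- lapply(parts, function(tr) {
    tr <- tr[order(tr$t), ]
    narx_design(tr$u, tr$y, spec, participant = tr$participant[1L],
                signal_id = tr$signal_id[1L])
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Split a participant's signals into training and test sets
#'
#' Follows the benchmark protocol: of the \code{n_signals} distinct
#' perturbation signals per participant the last (highest
#' \code{signal_id}) is the test signal and the rest form the training
#' set; cross-validation folds are the training signal ids
#' (leave-one-signal-out).
#'
#' @param trials data frame with columns \code{participant},
#'   \code{signal_id}, \code{t}, \code{u}, \code{y} for one participant.
#' @param n_signals expected number of distinct signals (reference
#'   protocol: 7, giving a 6-train/1-test split).
#' @return list with elements \code{train}, \code{test} (data frames) and
#'   \code{fold} (training signal id per training row).
#' @export
split_signals <- function(trials, n_signals = 7L) {
  ids <- sort(unique(trials$signal_id))
  if (length(ids) != n_signals)
    stop("expected ", n_signals, " distinct signals, found ", length(ids))
  if (n_signals < 2L) stop("need at least 2 signals to split")
  test_id <- ids[length(ids)]
  train <- trials[trials$signal_id != test_id, ]
  list(train = train, test = trials[trials$signal_id == test_id, ],
       fold = train$signal_id)
}

#' Read or write trial signals as delimited text
#'
#' The on-disk exchange format is a comma-separated file with header
#' \code{participant, signal_id, t, u, y}, one row per sample.
#'
#' @param path file path.
#' @return \code{read_trials} returns the data frame;
#'   \code{write_trials} returns \code{path} invisibly.
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path)
  need <- c("participant", "signal_id", "t", "u", "y")
  if (!all(need %in% names(d)))
    stop("trial file must have columns: ", paste(need, collapse = ", "))
  d
}

#' @rdname read_trials
#' @param trials data frame in the trial-signal layout.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
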
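#' Base-learner roster for the stacked ensemble
#'
#' Defines the five diverse layer-0 regressors and their hyperparameter
#' grids for the cross-validated grid search: LASSO (regularised linear
#' model), a single-hidden-layer MLP (sigmoid hidden units, identity
#' output), a Gaussian process and support-vector regression both with a
#' radial basis function kernel, and gradient boosting with a linear
#' booster. Grid contents are configurable; the defaults span the
#' magnitudes the reference study selected (LASSO regularisation up to
#' 0.9, 1/3/5 hidden units, kernel widths around 0.07, SVR cost up to 1,
#' 50/150 boosting rounds with learning rates 0.3/0.4 and L1/L2 penalties
#' up to 0.1).
#'
#' @param lasso_lambda LASSO regularisation grid.
#' @param mlp_size hidden-unit grid.
#' @param mlp_maxit MLP optimiser iteration cap (fixed setting).
#' @param gp_sigma,svr_sigma RBF kernel width grids.
#' @param svr_cost SVR cost grid.
#' @param xgb_nrounds,xgb_eta,xgb_lambda,xgb_alpha boosting grid: rounds,
#'   learning rate, L2 and L1 regularisation of the linear booster.
#' @return named list of five \code{"learner_spec"} objects
#'   (\code{LASSO}, \code{MLP}, \code{GP}, \code{SVR}, \code{XGBoost}),
#'   each with a \code{grid} data frame and \code{fit}/\code{predict}
#'   functions.
#' @export
stack_learners <- function(lasso_lambda = c(0.001, 0.01, 0.1, 0.9),
                           mlp_size = c(1, 3, 5), mlp_maxit = 300L,
                           gp_sigma = c(0.01, 0.03, 0.08, 0.2),
                           svr_sigma = c(0.01, 0.03, 0.08, 0.2),
                           svr_cost = c(0.25, 0.5, 1),
                           xgb_nrounds = c(50, 150), xgb_eta = c(0.3, 0.4),
                           xgb_lambda = c(0, 1e-4, 0.1),
                           xgb_alpha = c(0, 1e-4, 0.1)) {
  list(
    LASSO = learner_spec(
      "LASSO", data.frame(lambda = lasso_lambda),
      fit = function(x, y, params) {
        m <- glmnet::glmnet(x, y, alpha = 1, lambda = params$lambda)
        list(model = m, s = params$lambda)
      },
      predict = function(fit, x) drop(stats::predict(fit$model, x, s = fit$s))),
    MLP = learner_spec(
      "MLP", data.frame(size = mlp_size),
      fit = function(x, y, params) {
        ctr <- colMeans(x)
        scl <- apply(x, 2L, stats::sd)
        scl[scl == 0 | !is.finite(scl)] <- 1
        m <- nnet::nnet(scale(x, ctr, scl), y, size = params$size,
                        linout = TRUE, trace = FALSE, maxit = mlp_maxit,
                        MaxNWts = 5000L)
        list(model = m, center = ctr, scale = scl)
      },
      predict = function(fit, x)
        drop(stats::predict(fit$model, scale(x, fit$center, fit$scale)))),
    GP = learner_spec(
      "GP", data.frame(sigma = gp_sigma),
      fit = function(x, y, params)
        kernlab::gausspr(x, y, kernel = "rbfdot",
                         kpar = list(sigma = params$sigma)),
      predict = function(fit, x) drop(kernlab::predict(fit, x))),
    SVR = learner_spec(
      "SVR", expand.grid(sigma = svr_sigma, cost = svr_cost),
      fit = function(x, y, params)
        kernlab::ksvm(x, y, type = "eps-svr", kernel = "rbfdot",
                      kpar = list(sigma = params$sigma), C = params$cost),
      predict = function(fit, x) drop(kernlab::predict(fit, x))),
    XGBoost = learner_spec(
      "XGBoost", expand.grid(nrounds = xgb_nrounds, eta = xgb_eta,
                             lambda = xgb_lambda, alpha = xgb_alpha),
      fit = function(x, y, params)
        xgboost::xgb.train(
          params = list(booster = "gblinear", eta = params$eta,
                        lambda = params$lambda, alpha = params$alpha,
                        updater = "coord_descent",
                        objective = "reg:squarederror", nthread = 1L),
          data = xgboost::xgb.DMatrix(x, label = y),
          nrounds = params$nrounds, verbose = 0L),
      predict = function(fit, x)
        stats::predict(fit, xgboost::xgb.DMatrix(x)))
  )
}

learner_spec <- function(name, grid, fit, predict) {
  if (nrow(grid) == 0L) stop("empty hyperparameter grid for ", name)
  structure(list(name = name, grid = grid, fit = fit, predict = predict),
            class = "learner_spec")
}

#' Cross-validated grid search for one base learner
#'
#' Evaluates every grid point by leave-one-fold-out cross-validation,
#' selects the point with the smallest mean CV RMSE (first in grid order
#' on ties), keeps that point's out-of-fold predictions, and refits the
#' learner on all rows at the chosen point.
#'
#' @param spec a \code{"learner_spec"} from [stack_learners()].
#' @param x numeric regressor matrix.
#' @param y numeric response.
#' @param folds fold label per row (e.g. the training signal id).
#' @return list: \code{model} (refit on all rows), \code{params} (chosen
#'   grid row), \code{oof} (out-of-fold predictions at the chosen point),
#'   \code{cv_rmse} (its mean CV RMSE), \code{cv_rmse_grid} (all points),
#'   \code{spec}.
#' @export
grid_search_fit <- function(spec, x, y, folds) {
  grid <- spec$grid
  fold_ids <- unique(folds)
  if (length(fold_ids) < 2L) stop("need at least 2 folds")
  if (any(table(folds) < 2L)) stop("every fold needs at least 2 rows")
  n <- length(y)
  cv_pred <- matrix(NA_real_, n, nrow(grid))
  for (f in fold_ids) {
    tr <- folds != f
    for (g in seq_len(nrow(grid))) {
      m <- spec$fit(x[tr, , drop = FALSE], y[tr], grid[g, , drop = FALSE])
      cv_pred[!tr, g] <- spec$predict(m, x[!tr, , drop = FALSE])
    }
  }
  cv_rmse_grid <- vapply(seq_len(nrow(grid)), function(g)
    mean(vapply(fold_ids, function(f)
      rmse(y[folds == f], cv_pred[folds == f, g]), numeric(1L))),
    numeric(1L))
  best <- which.min(cv_rmse_grid)  # ties: first in grid order
  list(model = spec$fit(x, y, grid[best, , drop = FALSE]),
       params = grid[best, , drop = FALSE],
       oof = cv_pred[, best],
       cv_rmse = cv_rmse_grid[best],
       cv_rmse_grid = cv_rmse_grid,
       spec = spec)
}

#' Tune the rule-based meta-learner by maximising cross-validated VAF
#'
#' Searches the integer box committees in [0, committees_max] x neighbors
#' in [0, neighbors_max] for the pair maximising the mean leave-one-fold-
#' out VAF of the Cubist-style meta-learner on the out-of-fold base
#' predictions. The objective is evaluated through a per-fold cache that
#' grows committee members incrementally, so repeated evaluations (and
#' exhaustive enumeration) share fits.
#'
#' @param z out-of-fold base-learner prediction matrix (rows x learners).
#' @param y observed response.
#' @param folds fold label per row.
#' @param tuner \code{"jade"} (self-adaptive DE, default budget
#'   population 10 x 10 generations), \code{"de"} (classic DE,
#'   population 100), or \code{"grid"} (exhaustive enumeration of the
#'   integer grid).
#' @param committees_max,neighbors_max search-box upper bounds.
#' @param np,generations evolutionary budget (ignored by
#'   \code{"grid"}).
#' @param min_leaf,prune_tol passed to the rule-model fit.
#' @param backend optional external rule-model backend (see
#'   [cubist_rules()]); when given, the objective fits the backend model
#'   per evaluation instead of using the builtin incremental cache.
#' @param seed optional seed; \code{NULL} continues the current RNG
#'   stream.
#' @return list: \code{committees}, \code{neighbors}, \code{cv_vaf}
#'   (objective at the optimum), \code{result} (the \code{"jade_opt"}
#'   object, or the enumeration table for \code{"grid"}), and
#'   \code{objective} (the cached objective function of
#'   \code{c(committees, neighbors)}).
#' @export
tune_meta <- function(z, y, folds, tuner = c("jade", "de", "grid"),
                      committees_max = 60L, neighbors_max = 20L,
                      np = 10L, generations = 10L,
                      min_leaf = 8L, prune_tol = 0.01, backend = NULL,
                      seed = NULL) {
  tuner <- match.arg(tuner)
  z <- as.matrix(z)
  if (is.null(colnames(z))) colnames(z) <- paste0("x", seq_len(ncol(z)))
  obj <- if (is.null(backend)) {
    make_meta_objective(z, y, folds, min_leaf, prune_tol, neighbors_max)
  } else {
    function(par) {
      mean(vapply(unique(folds), function(f) {
        tr <- folds != f
        m <- cubist_rules(z[tr, , drop = FALSE], y[tr],
                          committees = as.integer(par[1L]),
                          neighbors = as.integer(par[2L]),
                          min_leaf = min_leaf, prune_tol = prune_tol,
                          backend = backend)
        vaf(y[!tr], predict(m, z[!tr, , drop = FALSE]))
      }, numeric(1L)))
    }
  }
  lower <- c(0, 0)
  upper <- c(committees_max, neighbors_max)
  if (tuner == "grid") {
    grid <- expand.grid(committees = 0:committees_max,
                        neighbors = 0:neighbors_max)
    val <- vapply(seq_len(nrow(grid)), function(i)
      obj(c(grid$committees[i], grid$neighbors[i])), numeric(1L))
    best <- which.max(val)
    return(list(committees = grid$committees[best],
                neighbors = grid$neighbors[best],
                cv_vaf = val[best],
                result = cbind(grid, cv_vaf = val),
                objective = obj, tuner = tuner))
  }
  res <- if (tuner == "jade") {
    jade(obj, lower, upper, np = np, generations = generations,
         maximize = TRUE, integer = c(TRUE, TRUE), seed = seed)
  } else {
    de_classic(obj, lower, upper, np = max(np, 100L),
               generations = generations, F = 0.2, CR = 0.5,
               maximize = TRUE, integer = c(TRUE, TRUE), seed = seed)
  }
  list(committees = as.integer(res$par[1L]),
       neighbors = as.integer(res$par[2L]),
       cv_vaf = res$value, result = res, objective = obj, tuner = tuner)
}

# Cross-validated meta objective with per-fold incremental committee
# caches: fitting cost is bounded by the largest committee count ever
# requested, not by the number of objective evaluations.
make_meta_objective <- function(z, y, folds, min_leaf, prune_tol, k_max) {
  fold_ids <- unique(folds)
  caches <- lapply(fold_ids, function(f) {
    tr <- which(folds != f)
    ho <- which(folds == f)
    ztr <- z[tr, , drop = FALSE]
    zho <- z[ho, , drop = FALSE]
    ctr <- colMeans(ztr)
    scl <- apply(ztr, 2L, stats::sd)
    if (any(scl == 0 | !is.finite(scl)))
      message("degenerate meta-input: constant out-of-fold column in a fold")
    scl[scl == 0 | !is.finite(scl)] <- 1
    d <- pairwise_dist(scale(zho, ctr, scl), scale(ztr, ctr, scl))
    kmax <- min(k_max, length(tr))
    ord <- t(apply(d, 1L, order))[, seq_len(kmax), drop = FALSE]
    nnd <- matrix(d[cbind(rep(seq_len(nrow(d)), kmax), as.vector(ord))],
                  ncol = kmax)
    env <- new.env(parent = emptyenv())
    env$ytr <- y[tr]; env$yho <- y[ho]
    env$ztr <- ztr; env$zho <- zho
    env$P_tr <- matrix(numeric(0), length(tr), 0L)
    env$P_ho <- matrix(numeric(0), length(ho), 0L)
    env$nn_idx <- ord; env$nn_d <- nnd
    env
  })
  ensure_members <- function(env, m) {
    while (ncol(env$P_tr) < m) {
      j <- ncol(env$P_tr) + 1L
      tgt <- if (j == 1L) env$ytr else
        env$ytr + (env$ytr - rowMeans(env$P_tr[, seq_len(j - 1L),
                                               drop = FALSE]))
      rm_ <- fit_rule_model(env$ztr, tgt, min_leaf, prune_tol)
      env$P_tr <- cbind(env$P_tr, predict_rule_model(rm_, env$ztr))
      env$P_ho <- cbind(env$P_ho, predict_rule_model(rm_, env$zho))
    }
  }
  function(par) {
    cc <- as.integer(par[1L])
    k <- as.integer(par[2L])
    m <- max(1L, cc)
    fold_vaf <- vapply(caches, function(env) {
      ensure_members(env, m)
      mh <- rowMeans(env$P_ho[, seq_len(m), drop = FALSE])
      if (k > 0L) {
        kk <- min(k, ncol(env$nn_idx))
        mt <- rowMeans(env$P_tr[, seq_len(m), drop = FALSE])
        pred <- numeric(length(mh))
        for (i in seq_along(mh)) {
          nn <- env$nn_idx[i, seq_len(kk)]
          vals <- env$ytr[nn] + mh[i] - mt[nn]
          w <- 1 / (env$nn_d[i, seq_len(kk)] + 0.5)
          pred[i] <- 0.5 * (mh[i] + sum(w * vals) / sum(w))
        }
      } else pred <- mh
      if (stats::var(env$yho) == 0) return(NA_real_)
      vaf(env$yho, pred)
    }, numeric(1L))
    mean(fold_vaf, na.rm = TRUE)
  }
}

#' Fit the tuned stacked ensemble for one participant
#'
#' End-to-end layer-0 + layer-1 training on one participant's signals:
#' the last signal is held out as the test set, the remaining signals are
#' pooled into the training design matrix with leave-one-signal-out
#' folds, every base learner is grid-searched by CV RMSE, their
#' out-of-fold predictions form the meta-input matrix, the rule-based
#' meta-learner's committees/neighbors pair is tuned by the chosen
#' optimiser on cross-validated VAF, and the meta-learner is refitted on
#' all training rows at the tuned pair. Meta-inputs at prediction time
#' come from the base learners refitted on all training rows.
#'
#' @param trials data frame (columns \code{participant},
#'   \code{signal_id}, \code{t}, \code{u}, \code{y}) for a single
#'   participant.
#' @param spec a [narx_spec()].
#' @param learners a [stack_learners()] roster.
#' @param tuner,committees_max,neighbors_max,np,generations,min_leaf,backend
#'   passed to [tune_meta()] and the final meta-learner fit.
#' @param n_signals expected signal count (default: as found).
#' @param seed integer seed; the whole fit is deterministic given it.
#' @return Object of class \code{"jade_stack"}; see
#'   [predict.jade_stack()], \code{summary}, \code{coef},
#'   \code{residuals}.
#' @export
jade_stack <- function(trials, spec = narx_spec(),
                       learners = stack_learners(),
                       tuner = c("jade", "de", "grid"),
                       committees_max = 60L, neighbors_max = 20L,
                       np = 10L, generations = 10L, min_leaf = 8L,
                       backend = NULL, n_signals = NULL, seed = 1L) {
  tuner <- match.arg(tuner)
  pid <- unique(trials$participant)
  if (length(pid) != 1L)
    stop("jade_stack fits one participant at a time; found ", length(pid))
  if (is.null(n_signals)) n_signals <- length(unique(trials$signal_id))
  set.seed(seed)

  sp <- split_signals(trials, n_signals)
  design <- build_designs(sp$train, spec)
  cols <- narx_columns(spec)
  x <- as.matrix(design[, cols])
  yv <- design$y
  folds <- design$signal_id

  layer0 <- lapply(learners, grid_search_fit, x = x, y = yv, folds = folds)
  z <- vapply(layer0, `[[`, numeric(length(yv)), "oof")
  colnames(z) <- names(layer0)

  tuning <- tune_meta(z, yv, folds, tuner = tuner,
                      committees_max = committees_max,
                      neighbors_max = neighbors_max,
                      np = np, generations = generations,
                      min_leaf = min_leaf, backend = backend, seed = NULL)
  meta <- cubist_rules(z, yv, committees = tuning$committees,
                       neighbors = tuning$neighbors, min_leaf = min_leaf,
                       backend = backend)

  fitted_cv <- predict(meta, z)
  structure(list(participant = pid, spec = spec, layer0 = layer0,
                 meta = meta, tuning = tuning[c("committees", "neighbors",
                                                "cv_vaf", "tuner")],
                 tuning_result = tuning$result,
                 folds = folds, y_train = yv,
                 fitted_cv = fitted_cv,
                 test_trial = sp$test, n_signals = n_signals,
                 seed = seed),
            class = "jade_stack")
}

# Layer-0 prediction matrix for a design-matrix block.
base_prediction_matrix <- function(object, x) {
  z <- vapply(object$layer0,
              function(l) l$spec$predict(l$model, x),
              numeric(nrow(x)))
  if (is.null(dim(z))) z <- matrix(z, nrow = nrow(x))
  colnames(z) <- names(object$layer0)
  z
}

# h-step recursive forecast of a generic one-step predictor over a
# signal: only the output lags are replaced by the model's own
# predictions; the input u is an exogenous designed perturbation, so all
# engineered u features stay computed from the known input.
recursive_forecast <- function(predict_fn, u, y, spec, h) {
  if (h < 1L) stop("horizon must be >= 1")
  design <- narx_design(u, y, spec)
  x0 <- as.matrix(design[, narx_columns(spec)])
  n <- length(y)
  b <- spec$burnin
  tt <- design$t
  pred_full <- matrix(NA_real_, n, h)  # pred_full[t, s] = s-step pred of y(t)
  pred_full[tt, 1L] <- predict_fn(x0)
  if (h > 1L) {
    for (s in 2:h) {
      ts <- (b + s):n
      xs <- x0[match(ts, tt), , drop = FALSE]
      for (j in seq_len(min(s - 1L, spec$ny)))
        xs[, paste0("y_lag", j)] <- pred_full[ts - j, s - j]
      pred_full[ts, s] <- predict_fn(xs)
    }
  }
  th <- (b + h):n
  list(t = th, y = y[th], yhat = pred_full[th, h])
}

#' Predict from a fitted stacked ensemble
#'
#' One-step-ahead prediction (\code{horizon = 1}) feeds the observed
#' lagged outputs through the refit base learners and the tuned
#' meta-learner. For \code{horizon = h > 1} the one-step predictor is
#' iterated recursively: the output-lag regressors beyond the forecast
#' origin are replaced by the model's own predictions (carrying forward
#' their errors), while the input-derived regressors always use the known
#' perturbation signal. The h-th-step predictions are reported aligned to
#' their target times.
#'
#' @param object a \code{"jade_stack"} fit.
#' @param newdata trial data frame (columns \code{t}, \code{u},
#'   \code{y}, optionally \code{signal_id}); defaults to the held-out
#'   test signal stored in the fit.
#' @param horizon forecast horizon h >= 1.
#' @param ... unused.
#' @return data frame: \code{participant}, \code{signal_id}, \code{t},
#'   \code{horizon}, \code{y}, \code{yhat}, \code{residual}.
#' @export
predict.jade_stack <- function(object, newdata = NULL, horizon = 1L, ...) {
  if (is.null(newdata)) newdata <- object$test_trial
  newdata <- newdata[order(newdata$t), ]
  sig <- if ("signal_id" %in% names(newdata)) newdata$signal_id[1L] else NA
  fn <- function(x) predict(object$meta, base_prediction_matrix(object, x))
  out <- recursive_forecast(fn, newdata$u, newdata$y, object$spec,
                            as.integer(horizon))
  data.frame(participant = object$participant, signal_id = sig,
             t = out$t, horizon = as.integer(horizon),
             y = out$y, yhat = out$yhat, residual = out$y - out$yhat)
}

#' @export
print.jade_stack <- function(x, ...) {
  cat(sprintf("jade_stack fit, participant %s (%d training signals + 1 test)\n",
              x$participant, x$n_signals - 1L))
  cat(sprintf("meta-learner (%s-tuned): committees = %d, neighbors = %d, CV VAF = %.2f\n",
              x$tuning$tuner, x$tuning$committees, x$tuning$neighbors,
              x$tuning$cv_vaf))
  invisible(x)
}

#' @export
summary.jade_stack <- function(object, ...) {
  base <- data.frame(
    learner = names(object$layer0),
    cv_rmse = vapply(object$layer0, `[[`, numeric(1L), "cv_rmse"),
    params = vapply(object$layer0, function(l)
      paste(sprintf("%s=%g", names(l$params), unlist(l$params)),
            collapse = ", "), character(1L)),
    row.names = NULL)
  structure(list(participant = object$participant, base = base,
                 tuning = object$tuning,
                 cv_vaf_stack = vaf(object$y_train, object$fitted_cv)),
            class = "summary.jade_stack")
}

#' @export
print.summary.jade_stack <- function(x, ...) {
  cat("stacked ensemble, participant", x$participant, "\n\nbase learners:\n")
  print(x$base, row.names = FALSE)
  cat(sprintf("\nmeta: committees = %d, neighbors = %d (tuner: %s)\n",
              x$tuning$committees, x$tuning$neighbors, x$tuning$tuner))
  cat(sprintf("tuned CV VAF = %.2f; meta on OOF inputs = %.2f\n",
              x$tuning$cv_vaf, x$cv_vaf_stack))
  invisible(x)
}

#' @export
coef.jade_stack <- function(object, ...) {
  c(committees = object$tuning$committees,
    neighbors = object$tuning$neighbors)
}

#' @export
residuals.jade_stack <- function(object, ...) {
  object$y_train - object$fitted_cv
}
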
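#' Cubist-style rule-based regression with committees and neighbors
#'
#' Fits a rule-based piecewise-linear regression model in the style of
#' Quinlan's Cubist: a variance-reduction model tree is grown and flattened
#' into mutually exclusive rules, each carrying a pruned linear model fitted
#' on the rows it covers; \emph{committees} iteratively refit the model on
#' boosting-like corrected pseudo-targets and average the members;
#' \emph{neighbors} blend the committee prediction with an instance-based
#' correction from the k nearest training cases. The two hyperparameters
#' \code{committees} and \code{neighbors} are exactly the knobs the
#' ensemble tuner searches over.
#'
#' This is a documented approximation sharing Cubist's hyperparameter
#' semantics, not a re-implementation of any particular Cubist release:
#' \code{committees = 0} and \code{committees = 1} both mean a single
#' member, \code{neighbors = 0} disables the instance-based correction.
#' An external rule-model implementation can be plugged in through
#' \code{backend} (a list with \code{fit(x, y, committees)} and
#' \code{predict(object, newdata, neighbors)} functions); the rest of the
#' package is agnostic to which backend produced the model.
#'
#' @param x numeric matrix (or data frame) of predictors.
#' @param y numeric response.
#' @param committees integer in [0, 60]: number of committee members.
#' @param neighbors integer in [0, 20]: default k for prediction.
#' @param min_leaf minimum rows per leaf of the model tree.
#' @param prune_tol a split is kept only if it reduces the node's squared
#'   error by at least this fraction.
#' @param backend optional external backend (see Details).
#' @return An object of class \code{"cubist_rules"} with a
#'   \code{predict} method.
#'
#' @examples
#' x <- matrix(runif(200), ncol = 2)
#' y <- 3 * x[, 1] + 1
#' m <- cubist_rules(x, y, committees = 1)
#' rmse(y, predict(m, x))  # near zero: a single (ridge-stabilised) rule
#' @export
cubist_rules <- function(x, y, committees = 1L, neighbors = 0L,
                         min_leaf = 8L, prune_tol = 0.01, backend = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  if (nrow(x) != length(y)) stop("x and y sizes disagree")
  committees <- as.integer(committees)
  neighbors <- as.integer(neighbors)
  if (committees < 0L || committees > 60L)
    stop("committees must lie in [0, 60]")
  if (neighbors < 0L || neighbors > 20L)
    stop("neighbors must lie in [0, 20]")

  if (!is.null(backend)) {
    obj <- backend$fit(x, y, committees = committees)
    return(structure(list(backend = backend, backend_object = obj,
                          committees = committees, neighbors = neighbors,
                          features = colnames(x)),
                     class = "cubist_rules"))
  }

  n_members <- max(1L, committees)
  members <- vector("list", n_members)
  pred_train <- matrix(0, nrow(x), n_members)
  target <- y
  for (j in seq_len(n_members)) {
    members[[j]] <- fit_rule_model(x, target, min_leaf, prune_tol)
    pred_train[, j] <- predict_rule_model(members[[j]], x)
    if (j < n_members) {
      running <- rowMeans(pred_train[, seq_len(j), drop = FALSE])
      target <- y + (y - running)
    }
  }

  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  structure(list(members = members, committees = committees,
                 neighbors = neighbors, features = colnames(x),
                 min_leaf = min_leaf, prune_tol = prune_tol,
                 center = ctr, scale = scl,
                 train_x_std = scale(x, ctr, scl),
                 train_y = y,
                 train_pred = rowMeans(pred_train)),
            class = "cubist_rules")
}

#' Predict from a Cubist-style rule model
#'
#' With \code{neighbors = 0} the prediction is the committee average
#' m(x). With \code{neighbors = k >= 1} the k nearest training rows
#' (Euclidean distance on features standardised by training mean/sd)
#' contribute adjusted values \code{y_n + m(x) - m(x_n)} weighted by
#' \code{1 / (distance + 0.5)}; their weighted mean is blended 50/50 with
#' m(x). A k exceeding the number of training rows is clamped.
#'
#' @param object a \code{"cubist_rules"} model.
#' @param newdata numeric matrix or data frame with the training columns.
#' @param neighbors k for the instance-based correction; defaults to the
#'   value the model was fitted with.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.cubist_rules <- function(object, newdata,
                                 neighbors = object$neighbors, ...) {
  newx <- as.matrix(newdata)
  if (!is.null(colnames(newx)) && all(object$features %in% colnames(newx))) {
    newx <- newx[, object$features, drop = FALSE]
  } else if (ncol(newx) == length(object$features)) {
    colnames(newx) <- object$features
  } else {
    stop("newdata columns do not match the fitted model")
  }
  storage.mode(newx) <- "double"

  if (!is.null(object$backend))
    return(object$backend$predict(object$backend_object, newx,
                                  neighbors = neighbors))

  P <- vapply(object$members, function(rm) predict_rule_model(rm, newx),
              numeric(nrow(newx)))
  if (is.null(dim(P))) P <- matrix(P, nrow = nrow(newx))
  m <- rowMeans(P)
  k <- as.integer(neighbors)
  if (k <= 0L) return(m)
  n_train <- nrow(object$train_x_std)
  if (k > n_train) {
    message("neighbors clamped from ", k, " to ", n_train, " training rows")
    k <- n_train
  }
  xs <- scale(newx, object$center, object$scale)
  d <- pairwise_dist(xs, object$train_x_std)
  out <- numeric(nrow(newx))
  for (i in seq_len(nrow(newx))) {
    nn <- order(d[i, ])[seq_len(k)]
    val <- object$train_y[nn] + m[i] - object$train_pred[nn]
    w <- 1 / (d[i, nn] + 0.5)
    out[i] <- 0.5 * (m[i] + sum(w * val) / sum(w))
  }
  out
}

#' @export
print.cubist_rules <- function(x, ...) {
  if (!is.null(x$backend)) {
    cat("cubist_rules (external backend), committees =", x$committees,
        ", neighbors =", x$neighbors, "\n")
    return(invisible(x))
  }
  nr <- vapply(x$members, function(m) length(m$rules), integer(1L))
  cat(sprintf("cubist_rules: %d member(s), %s rule(s)/member, neighbors = %d\n",
              length(x$members), paste(range(nr), collapse = "-"),
              x$neighbors))
  invisible(x)
}

#' Export a fitted rule set as human-readable text
#'
#' One block per rule: its conditions, the coefficients of its linear
#' model, and the number of training rows it covers.
#'
#' @param object a \code{"cubist_rules"} model (builtin backend).
#' @return character vector, one element per line.
#' @export
rules_text <- function(object) {
  stopifnot(inherits(object, "cubist_rules"), is.null(object$backend))
  out <- character(0)
  for (j in seq_along(object$members)) {
    out <- c(out, sprintf("== member %d ==", j))
    rs <- object$members[[j]]$rules
    for (r in seq_along(rs)) {
      rl <- rs[[r]]
      cond <- if (length(rl$conditions) == 0L) "(always)" else
        paste(vapply(rl$conditions, function(cd)
          sprintf("%s %s %.6g", cd$feature, cd$op, cd$threshold),
          character(1L)), collapse = " & ")
      show <- rl$coef[rl$coef != 0 | names(rl$coef) == "(Intercept)"]
      cf <- paste(sprintf("%s=%.6g", names(show), show), collapse = " ")
      out <- c(out, sprintf("rule %d [cover %d]: %s", r, rl$cover, cond),
               paste0("  ", cf))
    }
  }
  out
}

## --- internal: model tree -> rules ---------------------------------------

# Fit one rule model, M5-style: (1) grow a variance-reduction model tree
# with a coefficient-pruned linear model at every node; (2) post-prune
# bottom-up, collapsing any split whose node model has no worse adjusted
# error than the cover-weighted error of its subtree; (3) smooth each
# surviving leaf's model with its ancestors' models on the way down
# (weights cover : smooth_k), the standard guard against small-leaf
# overfitting; (4) flatten the smoothed leaves to rules. Because every
# node model is linear, each smoothed leaf model is again linear with
# closed-form coefficients.
fit_rule_model <- function(x, y, min_leaf = 8L, prune_tol = 0.01,
                           smooth_k = 15) {
  feats <- colnames(x)
  fit_node <- function(idx) {
    f <- fit_pruned_lm(x[idx, , drop = FALSE], y[idx])
    list(coef = full_coef(f$coef, feats), crit = f$crit)
  }
  grow <- function(idx, depth) {
    nf <- fit_node(idx)
    node <- list(idx = idx, coef = nf$coef, crit = nf$crit, split = NULL)
    yy <- y[idx]
    sse <- sum((yy - mean(yy))^2)
    if (length(idx) >= 2L * min_leaf && sse > 0 && depth < 12L) {
      sp <- best_split(x[idx, , drop = FALSE], yy, min_leaf)
      if (!is.null(sp) && (sse - sp$sse) >= prune_tol * sse) {
        go_left <- x[idx, sp$j] <= sp$threshold
        node$split <- list(j = sp$j, threshold = sp$threshold,
                           left = grow(idx[go_left], depth + 1L),
                           right = grow(idx[!go_left], depth + 1L))
      }
    }
    node
  }
  prune <- function(node) {
    if (is.null(node$split)) {
      node$sub_crit <- node$crit
      return(node)
    }
    node$split$left <- prune(node$split$left)
    node$split$right <- prune(node$split$right)
    nl <- length(node$split$left$idx)
    nr <- length(node$split$right$idx)
    sub <- (nl * node$split$left$sub_crit + nr * node$split$right$sub_crit) /
      (nl + nr)
    if (node$crit <= sub * (1 + 1e-8) + 1e-12) {
      node$split <- NULL
      node$sub_crit <- node$crit
    } else node$sub_crit <- sub
    node
  }
  root <- prune(grow(seq_len(nrow(x)), 0L))
  rules <- list()
  flatten <- function(node, conds, parent_sm) {
    sm <- if (is.null(parent_sm)) node$coef else
      (length(node$idx) * node$coef + smooth_k * parent_sm) /
      (length(node$idx) + smooth_k)
    if (is.null(node$split)) {
      rules[[length(rules) + 1L]] <<- list(conditions = conds, coef = sm,
                                           cover = length(node$idx))
    } else {
      feat <- feats[node$split$j]
      thr <- node$split$threshold
      flatten(node$split$left,
              c(conds, list(list(feature = feat, op = "<=",
                                 threshold = thr))), sm)
      flatten(node$split$right,
              c(conds, list(list(feature = feat, op = ">",
                                 threshold = thr))), sm)
    }
  }
  flatten(root, list(), NULL)
  list(rules = rules, fallback = root$coef, features = feats,
       y_range = range(y))
}

# Expand a pruned coefficient vector to the full (Intercept, features)
# layout with zeros for dropped predictors.
full_coef <- function(cf, feats) {
  out <- stats::setNames(numeric(length(feats) + 1L),
                         c("(Intercept)", feats))
  out[names(cf)] <- cf
  out
}

# Best axis-aligned split by total child SSE, respecting min_leaf.
best_split <- function(x, y, min_leaf) {
  n <- length(y)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    xo <- x[o, j]
    yo <- y[o]
    cs <- cumsum(yo)
    cs2 <- cumsum(yo^2)
    m <- seq_len(n - 1L)
    valid <- m >= min_leaf & (n - m) >= min_leaf & xo[m] < xo[m + 1L]
    if (!any(valid)) next
    sse_l <- cs2[m] - cs[m]^2 / m
    sse_r <- (cs2[n] - cs2[m]) - (cs[n] - cs[m])^2 / (n - m)
    tot <- sse_l + sse_r
    tot[!valid] <- Inf
    mb <- which.min(tot)
    if (is.null(best) || tot[mb] < best$sse)
      best <- list(j = j, threshold = (xo[mb] + xo[mb + 1L]) / 2,
                   sse = tot[mb])
  }
  best
}

# Node linear model: ridge-stabilised least squares on standardised
# predictors (lambda = lambda_rel * n, i.e. a fixed small shrinkage
# fraction) followed by one coefficient-pruning pass that drops
# predictors contributing less than 1% of the response spread. The ridge
# floor is what keeps node models sane when the predictors are strongly
# collinear (as stacked base-learner predictions are): coefficients
# along near-null data directions are shrunk away instead of exploding,
# while well-determined directions are biased by only ~lambda_rel.
# Returns the coefficient vector and the adjusted-error criterion
# mean|r| * (n + p) / (n - p) used by the tree pruner.
fit_pruned_lm <- function(x, y, lambda_rel = 0.01) {
  n <- length(y)
  sdy <- stats::sd(y)
  scl <- apply(x, 2L, stats::sd)
  active <- colnames(x)[scl > 0 & is.finite(scl)]
  if (n < 3L || length(active) == 0L || is.na(sdy) || sdy == 0)
    return(list(coef = c("(Intercept)" = mean(y)),
                crit = adj_err(abs(y - mean(y)), n, 1L)))
  ridge <- function(vars) {
    if (length(vars) == 0L) {
      return(list(coef = c("(Intercept)" = mean(y)), std_slopes = numeric(0),
                  crit = adj_err(abs(y - mean(y)), n, 1L)))
    }
    xs <- scale(x[, vars, drop = FALSE])
    ctr <- attr(xs, "scaled:center")
    s <- attr(xs, "scaled:scale")
    yc <- y - mean(y)
    G <- crossprod(xs) + diag(lambda_rel * n, ncol(xs))
    bs <- drop(solve(G, crossprod(xs, yc)))
    slopes <- bs / s
    cf <- c("(Intercept)" = mean(y) - sum(slopes * ctr), slopes)
    names(cf) <- c("(Intercept)", vars)
    resid <- y - drop(cbind(1, x[, vars, drop = FALSE]) %*% cf)
    list(coef = cf, std_slopes = stats::setNames(bs, vars),
         crit = adj_err(abs(resid), n, length(vars) + 1L))
  }
  f1 <- ridge(active)
  strong <- names(f1$std_slopes)[abs(f1$std_slopes) >= 0.01 * sdy]
  f <- if (length(strong) < length(active)) ridge(strong) else f1
  list(coef = f$coef, crit = f$crit)
}

adj_err <- function(abs_resid, n, p) {
  if (n - p <= 0L) return(Inf)
  mean(abs_resid) * (n + p) / (n - p)
}

predict_rule_model <- function(rm, newx) {
  if (is.null(colnames(newx))) colnames(newx) <- rm$features
  n <- nrow(newx)
  out <- rep(NA_real_, n)
  for (rl in rm$rules) {
    mask <- rep(TRUE, n)
    for (cd in rl$conditions) {
      v <- newx[, cd$feature]
      mask <- mask & if (cd$op == "<=") v <= cd$threshold else v > cd$threshold
    }
    mask <- mask & is.na(out)
    if (any(mask)) out[mask] <- eval_linear(rl$coef, newx[mask, , drop = FALSE])
  }
  miss <- is.na(out)
  if (any(miss)) out[miss] <- eval_linear(rm$fallback,
                                          newx[miss, , drop = FALSE])
  # extrapolation guard: predictions are truncated to the training target
  # range extended by half its span. The margin is deliberately wide —
  # held-out signals legitimately reach beyond the training extremes, so
  # the guard only stops runaway linear extrapolation, not ordinary
  # out-of-range predictions.
  span <- diff(rm$y_range)
  pmin(pmax(out, rm$y_range[1L] - 0.5 * span),
       rm$y_range[2L] + 0.5 * span)
}

eval_linear <- function(cf, newx) {
  out <- rep(cf[["(Intercept)"]], nrow(newx))
  slopes <- cf[setdiff(names(cf), "(Intercept)")]
  if (length(slopes) > 0L)
    out <- out + drop(newx[, names(slopes), drop = FALSE] %*% slopes)
  out
}

pairwise_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
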
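# Shared helpers: small-scale study configurations and a lazily built,
# cached benchmark/fit pair reused across test files (fitting the full
# stack is the expensive step).

tiny_mspec <- function(seconds = 2) {
  multisine_spec(fs = 64, seconds = seconds, harmonics = 1:6)
}

# Reduced hyperparameter grids: same learners, fewer grid points; used by
# multi-seed simulation tests where the grid breadth is not the property
# under test.
lite_learners <- function() {
  stack_learners(gp_sigma = c(0.03, 0.08), svr_sigma = c(0.03, 0.08),
                 svr_cost = 1, xgb_nrounds = 100, xgb_eta = 0.3,
                 xgb_lambda = c(0, 0.1), xgb_alpha = 0)
}

.jadestack_cache <- new.env(parent = emptyenv())

cached_bench <- function() {
  if (is.null(.jadestack_cache$bench))
    .jadestack_cache$bench <- synth_benchmark(1, tiny_mspec(), sigma = 0.05,
                                              seed = 3)
  .jadestack_cache$bench
}

cached_fit <- function() {
  if (is.null(.jadestack_cache$fit))
    .jadestack_cache$fit <- jade_stack(cached_bench()$trials, seed = 11)
  .jadestack_cache$fit
}

# Small (z, y, folds) regression problem for meta-learner tests.
make_meta_problem <- function(n = 180, seed = 7, noise = 0.1) {
  set.seed(seed)
  truth <- runif(n, -2, 2)
  z <- cbind(truth + rnorm(n, 0, 0.2), truth + rnorm(n, 0, 0.3),
             truth + rnorm(n, 0, 0.4))
  colnames(z) <- c("a", "b", "c")
  y <- truth + rnorm(n, 0, noise)
  list(z = z, y = y, folds = rep(1:3, length.out = n))
}
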
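# Shared fixtures and oracles.
#
# numeric_grad: central-difference gradient of f at v[i]; kernels run in
# single precision, so checks use eps = 1e-3 and a few-percent tolerance on
# gradients of non-negligible magnitude.

numeric_grad <- function(f, v, i, eps = 1e-3) {
  v1 <- v; v2 <- v
  v1[i] <- v1[i] + eps
  v2[i] <- v2[i] - eps
  (f(v1) - f(v2)) / (2 * eps)
}

# check analytic vs numeric gradients on a sample of indices; gradients with
# |numeric| below `floor` are skipped (dominated by float noise)
expect_grad_close <- function(f, v, analytic, idx, tol = 0.05, floor = 5e-3) {
  for (i in idx) {
    ng <- numeric_grad(f, v, i)
    if (abs(ng) < floor) next
    expect_lt(abs(ng - analytic[i]) / (abs(ng) + abs(analytic[i])), tol)
  }
}

small_stack <- function(seed = 1, side = 64, nmod = 2) {
  generateCase(phantomSpec(imageSide = side, nModalities = nmod, seed = seed))
}

# memoised smoke-training runs shared between the engine and acceptance
# tests (the conditions: 200 training slices, 50 held out, side 64, base
# filters 8, 10 epochs)
.smoke_cache <- new.env(parent = emptyenv())

smoke_conditions <- function() {
  list(n_train = 200L, n_holdout = 50L, side = 64L, base_filters = 8L,
       epochs = 10L, lr = 1e-3, seed = 42L)
}

get_smoke_fit <- function(selfsup = TRUE) {
  key <- if (selfsup) "selfsup" else "plain"
  if (!is.null(.smoke_cache[[key]])) return(.smoke_cache[[key]])
  sc <- smoke_conditions()
  train <- phantomDataset(sc$n_train, phantomSpec(imageSide = sc$side,
                                                  seed = 1000L))
  hold <- phantomDataset(sc$n_holdout, phantomSpec(imageSide = sc$side,
                                                    seed = 9000L))
  cfg <- networkConfig(baseFilters = sc$base_filters)
  fit <- trainNetwork(train, cfg,
                      trainConfig(epochs = sc$epochs, initialLr = sc$lr,
                                  seed = sc$seed, selfsup = selfsup))
  ev <- evaluateOnDataset(fit, hold)
  .smoke_cache[[key]] <- list(fit = fit, eval = ev, holdout = hold)
  .smoke_cache[[key]]
}
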
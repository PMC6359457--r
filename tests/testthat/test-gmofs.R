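random_model <- function(n, p, K, seed) {
  set.seed(seed)
  gmofs_model(runif(n, 0.1, 0.9),
              matrix(runif((n + 1) * (p - 1), -0.6, 0.6), n + 1, p - 1),
              matrix(runif(p * K, -0.6, 0.6), p, K))
}

test_that("forward pass: multiplicative input gating and hand arithmetic", {
  mod <- random_model(3, 4, 2, seed = 1)
  # beta = 0 blocks all inputs: output independent of x
  mod0 <- gmofs_model(rep(0, 3), mod$V, mod$W)
  o1 <- gmofs_forward(mod0, c(1, 2, 3))
  o2 <- gmofs_forward(mod0, c(-5, 0, 100))
  expect_equal(o1, o2)

  # hand-computed 2-input / 2-hidden(incl. bias) / 1-output composition
  beta <- c(1, 1)
  V <- matrix(c(0.2, -0.1, 0.05), 3, 1)      # rows: x1, x2, input bias
  W <- matrix(c(0.3, -0.2), 2, 1)            # rows: hidden unit, bias node
  m <- gmofs_model(beta, V, W)
  x <- c(0.5, -1)
  h <- 1 / (1 + exp(-(0.2 * 0.5 - 0.1 * -1 + 0.05)))
  expect_equal(unname(gmofs_forward(m, x)),
               1 / (1 + exp(-(0.3 * h - 0.2))), tolerance = 1e-12)

  # scaling x_i by c and beta_i by 1/c leaves the output unchanged
  c_ <- 2.5
  mods <- gmofs_model(mod$beta / c_, mod$V, mod$W)
  expect_equal(gmofs_forward(mod, c(1, 2, 3)),
               gmofs_forward(mods, c_ * c(1, 2, 3)))
})

test_that("cost: squared error plus elastic-net penalty on beta", {
  mod <- random_model(2, 3, 2, seed = 2)
  X <- matrix(rnorm(10), 5, 2)
  T <- one_hot_targets(rep(c("a", "b"), length.out = 5))
  O <- gmofs_forward(mod, X)
  expect_equal(gmofs_cost(mod, X, T, 0, 0.5), 0.5 * sum((T - O)^2))

  # perfect outputs, beta = 0.5, alpha = 0.5, lambda = 2 -> penalty only
  m1 <- gmofs_model(0.5, matrix(0, 2, 2), matrix(0, 3, 1))
  X1 <- matrix(0, 1, 1)
  T1 <- gmofs_forward(m1, X1)  # o = t exactly
  expect_equal(gmofs_cost(m1, X1, matrix(T1, 1, 1), 2, 0.5),
               2 * (0.5 * 0.25 + 0.5 * 0.5))  # = 0.75

  # alpha = 0: pure lasso penalty lambda * sum(beta)
  expect_equal(gmofs_cost(mod, X, T, 3, 0) - gmofs_cost(mod, X, T, 0, 0),
               3 * sum(mod$beta))
})

test_that("analytic gradients agree with central finite differences", {
  # the gradient oracle: 20 random small instances, beta away from 0
  worst <- 0
  for (inst in 1:20) {
    set.seed(100 + inst)
    n <- sample(2:5, 1); p <- sample(2:4, 1); K <- sample(1:3, 1)
    m <- sample(3:8, 1)
    mod <- random_model(n, p, K, seed = 200 + inst)
    X <- matrix(rnorm(m * n), m, n)
    T <- matrix(runif(m * K, 0.05, 0.95), m, K)
    lam <- runif(1, 0, 3); al <- runif(1)
    g <- gmofs_gradients(mod, X, T, lam, al)
    an <- c(g$beta, g$V, g$W)
    th <- c(mod$beta, mod$V, mod$W)
    eps <- 1e-5   # central differences: truncation ~eps^2, roundoff ~mach/eps
    unpack <- function(t) gmofs_model(t[1:n],
      matrix(t[n + seq_len((n + 1) * (p - 1))], n + 1, p - 1),
      matrix(t[n + (n + 1) * (p - 1) + seq_len(p * K)], p, K))
    fd <- vapply(seq_along(th), function(i) {
      tp <- th; tm <- th
      tp[i] <- tp[i] + eps; tm[i] <- tm[i] - eps
      (gmofs_cost(unpack(tp), X, T, lam, al) -
         gmofs_cost(unpack(tm), X, T, lam, al)) / (2 * eps)
    }, 0)
    rel <- max(abs(an - fd) / pmax(abs(fd), 1e-4))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-6)
})

test_that("gradient structure: lasso term, stationary perfect fit", {
  mod <- random_model(3, 3, 2, seed = 5)
  X <- matrix(rnorm(12), 4, 3)
  T <- one_hot_targets(rep(c("a", "b"), 2))
  g0 <- gmofs_gradients(mod, X, T, 0, 0)
  g1 <- gmofs_gradients(mod, X, T, 7, 0)
  expect_equal(g1$beta - g0$beta, rep(7, 3))  # +lambda per beta_i > 0

  # at o = t with lambda = 0 every gradient vanishes
  O <- gmofs_forward(mod, X)
  gz <- gmofs_gradients(mod, X, O, 0, 0)
  expect_equal(max(abs(c(gz$beta, gz$V, gz$W))), 0)
})

test_that("constrained training respects bounds and decreases the cost", {
  set.seed(8)
  tab <- separable_table(m = 60, n = 5, informative = 1, classes = 2,
                         effect = 6, seed = 21)
  tab <- normalize_table(tab)
  T <- one_hot_targets(tab$labels)
  cfg <- gmofs_config(hidden_nodes = 4, lambda_grid = c(0, 1), seed = 3)
  for (lam in c(0, 0.5, 3)) {
    mod <- train_constrained(tab$values, T, lam, cfg, seed = 30 + lam)
    expect_true(all(mod$beta >= 0 & mod$beta <= 1))
    expect_true(all(abs(mod$V) <= cfg$weight_bound_b + 1e-12))
    expect_true(all(abs(mod$W) <= cfg$weight_bound_a + 1e-12))
    expect_lte(attr(mod, "cost"), attr(mod, "initial_cost"))
  }
})

test_that("the planted informative feature attains the largest beta", {
  # 1 informative + 4 pure-noise features, separable classes, moderate lambda;
  # informativeness verified by exhaustive single-feature classifier error
  # lambda is moderate relative to the summed-error scale (lambda/m ~ 0.005,
  # the mid-path regime; the error term of the cost grows with m)
  tab <- separable_table(m = 400, n = 5, informative = 1, classes = 2,
                         effect = 6, seed = 33)
  ntab <- normalize_table(tab)
  ev <- make_subset_evaluator(ntab, "lda", folds = 5, seed = 1)
  single_errs <- vapply(1:5, function(j) ev(j), 0)
  expect_identical(which.min(single_errs), 1L)  # feature 1 is the informative one

  T <- one_hot_targets(ntab$labels)
  cfg <- gmofs_config(hidden_nodes = 4, lambda_grid = c(2), seed = 1)
  hits <- vapply(1:10, function(s) {
    mod <- train_constrained(ntab$values, T, 2, cfg, seed = 500 + s)
    mod$beta[1] > 0 && which.max(mod$beta) == 1
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("select_significant implements the cumulative threshold rule", {
  expect_identical(select_significant(c(0.9, 0.05, 0.05), 0.95), c(1L, 2L))
  expect_identical(select_significant(rep(0.3, 10), 0.95), 1:10)
  expect_identical(select_significant(0.2, 0.5), 1L)
  # equal betas: tie broken by lower original index; top-2 share is 100%
  expect_identical(select_significant(c(0.5, 0.5, 0), 0.95), c(1L, 2L))
  expect_error(select_significant(c(0, 0, 0)), "all-zero")
  expect_error(select_significant(c(-0.1, 0.5)), "non-negative")
})

test_that("lambda grid construction and parsing", {
  expect_length(default_lambda_grid(), 43)
  expect_identical(parse_lambda_grid("0:1:30,40:10:150"), default_lambda_grid())
  expect_error(parse_lambda_grid("10:1:20,0:1:5"), "non-decreasing")
})

test_that("run_gmofs sweeps the grid and extracts a clean Pareto front", {
  tab <- normalize_table(separable_table(m = 120, n = 10, informative = 1:3,
                                         classes = 3, effect = 6, seed = 44))
  ev <- make_subset_evaluator(tab, "lda", folds = 5, seed = 2)
  grid <- c(0, 1, 2, 4, 8, 15, 25)
  res <- run_gmofs(tab, gmofs_config(lambda_grid = grid, seed = 7), ev)
  expect_identical(nrow(res$records), length(grid))
  # shrinkage: subset at the largest lambda no larger than at lambda = 0
  sizes <- res$records$f1[!res$records$flagged]
  lams <- res$records$lambda[!res$records$flagged]
  expect_lte(sizes[which.max(lams)], sizes[which.min(lams)])
  # front mutually non-dominated, equal to the brute-force filter
  obj <- res$pareto$objectives
  expect_true(all(brute_pareto_keep(obj)))
  # every pareto payload references a lambda record
  for (p in res$pareto$payloads) {
    k <- which(res$records$lambda == p$lambda)[1]
    expect_identical(sort(p$subset), sort(res$subsets[[k]]))
  }
})
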
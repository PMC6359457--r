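#' GMOFS configuration
#'
#' Settings for gradient-based multi-objective feature selection: a
#' constrained single-hidden-layer perceptron whose per-feature input
#' multipliers `beta` carry an elastic-net penalty
#' `lambda * sum(alpha * beta^2 + (1 - alpha) * abs(beta))`, trained once per
#' value of the regularization grid.
#'
#' Defaults follow the reference tuning: `p = 5` hidden nodes (including the
#' bias node), `alpha = 0` (pure lasso), lambda grid step 1 on `[0, 30]` and
#' step 10 on `(30, 150]` (43 values), weight bounds `a = b = 5`, selection
#' threshold 95%, optimizer budget 100 iterations with tolerances 0.001.
#'
#' @param hidden_nodes total hidden nodes p, including the bias node (>= 2).
#' @param alpha elastic-net mix in `[0, 1]`: 1 = ridge, 0 = lasso.
#' @param lambda_grid non-decreasing vector of lambda values (>= 0).
#' @param weight_bound_a bound on hidden-to-output weights `|w| <= a`.
#' @param weight_bound_b bound on input-to-hidden weights `|v| <= b`.
#' @param threshold cumulative input-weight fraction theta in `(0, 1]`.
#' @param max_iter,tol_x,tol_fun optimizer budget and tolerances.
#' @param target_lo,target_hi one-hot target encoding values (sigmoid
#'   outputs cannot reach 0/1 exactly; 0.05/0.95 keeps weights off the
#'   bounds).
#' @param warm_start initialize each lambda's training from the previous
#'   lambda's solution (standard for regularization paths; stabilizes the
#'   shrinkage profile). The first lambda always uses the seeded random
#'   init; `FALSE` re-initializes randomly at every lambda.
#' @param seed integer seed for initialization.
#' @return an object of class `gmofs_config`.
#' @export
gmofs_config <- function(hidden_nodes = 5L, alpha = 0,
                         lambda_grid = default_lambda_grid(),
                         weight_bound_a = 5, weight_bound_b = 5,
                         threshold = 0.95, max_iter = 100L,
                         tol_x = 1e-3, tol_fun = 1e-3,
                         target_lo = 0.05, target_hi = 0.95,
                         warm_start = TRUE, seed = 1L) {
  if (alpha < 0 || alpha > 1) stop_config("alpha must be in [0, 1]")
  if (threshold <= 0 || threshold > 1) stop_config("threshold must be in (0, 1]")
  if (is.unsorted(lambda_grid)) stop_config("lambda grid must be non-decreasing")
  if (any(lambda_grid < 0)) stop_config("lambda values must be >= 0")
  if (hidden_nodes < 2) stop_config("need >= 2 hidden nodes (one is the bias)")
  if (weight_bound_a <= 0 || weight_bound_b <= 0)
    stop_config("weight bounds must be positive")
  structure(list(hidden_nodes = as.integer(hidden_nodes), alpha = alpha,
                 lambda_grid = lambda_grid, weight_bound_a = weight_bound_a,
                 weight_bound_b = weight_bound_b, threshold = threshold,
                 max_iter = as.integer(max_iter), tol_x = tol_x,
                 tol_fun = tol_fun, target_lo = target_lo,
                 target_hi = target_hi, warm_start = isTRUE(warm_start),
                 seed = as.integer(seed)),
            class = "gmofs_config")
}

#' Reference lambda grid
#'
#' Step 1 on `[0, 30]` and step 10 on `(30, 150]`: 31 + 12 = 43 values, one
#' constrained training per value.
#'
#' @return numeric vector of 43 lambda values.
#' @export
default_lambda_grid <- function() c(0:30, seq(40, 150, by = 10))

#' Parse a lambda-grid string
#'
#' Accepts comma-separated `from:by:to` segments, e.g. `"0:1:30,40:10:150"`.
#'
#' @param spec grid string.
#' @return numeric vector.
#' @export
parse_lambda_grid <- function(spec) {
  segs <- strsplit(spec, ",", fixed = TRUE)[[1]]
  grid <- unlist(lapply(segs, function(s) {
    p <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
    if (length(p) == 1) return(p)
    if (length(p) != 3 || any(is.na(p))) stop_config("bad grid segment '%s'", s)
    seq(p[1], p[3], by = p[2])
  }))
  if (is.unsorted(grid)) stop_config("lambda grid must be non-decreasing")
  grid
}

#' Constrained-MLP model container
#'
#' `beta` holds the per-feature input multipliers in `[0, 1]`; `V` the
#' input-to-hidden weights (rows: n inputs plus one input-bias row, columns:
#' the p - 1 sigmoid hidden units); `W` the hidden-to-output weights (rows:
#' p hidden nodes, the last being the constant-1 bias node; columns: K
#' outputs).
#'
#' @param beta numeric vector in `[0, 1]^n`.
#' @param V (n + 1) x (p - 1) weight matrix, `|V| <= b`.
#' @param W p x K weight matrix, `|W| <= a`.
#' @return an object of class `gmofs_model`.
#' @export
gmofs_model <- function(beta, V, W) {
  n <- length(beta); H <- ncol(V); p <- H + 1L; K <- ncol(W)
  if (nrow(V) != n + 1L) stop_config("V must have n + 1 rows")
  if (nrow(W) != p) stop_config("W must have p = ncol(V) + 1 rows")
  structure(list(beta = beta, V = V, W = W, n = n, p = p, K = K),
            class = "gmofs_model")
}

#' @export
print.gmofs_model <- function(x, ...) {
  cat(sprintf("gmofs_model: %d inputs, %d hidden nodes (incl. bias), %d outputs\n",
              x$n, x$p, x$K))
  invisible(x)
}

# forward pass returning intermediates for backprop
forward_full <- function(model, X) {
  Z <- sweep(X, 2, model$beta, "*")
  Zaug <- cbind(Z, 1)
  Yh <- sigmoid(Zaug %*% model$V)        # m x (p-1)
  Y <- cbind(Yh, 1)                      # bias node fixed at 1
  O <- sigmoid(Y %*% model$W)            # m x K
  list(Zaug = Zaug, Yh = Yh, Y = Y, O = O)
}

#' Forward pass of the constrained MLP
#'
#' Inputs are scaled elementwise by `beta`, a constant-1 input bias is
#' appended, the result passes through `p - 1` sigmoid hidden units plus the
#' constant-1 bias node, then through sigmoid output units.
#'
#' @param model a [gmofs_model()].
#' @param x a length-n feature vector or an m x n pattern matrix.
#' @return output vector in `(0, 1)^K` (or m x K matrix).
#' @export
gmofs_forward <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != model$n)
    stop_config("expected %d inputs, got %d", model$n, ncol(X))
  O <- forward_full(model, X)$O
  if (is.matrix(x)) O else drop(O)
}

penalty <- function(beta, lambda, alpha)
  lambda * sum(alpha * beta^2 + (1 - alpha) * abs(beta))

#' Elastic-net-penalized training cost
#'
#' `J = 1/2 sum_l sum_j (t_j(l) - o_j(l))^2 +
#'  lambda sum_i (alpha beta_i^2 + (1 - alpha) |beta_i|)`.
#'
#' @param model a [gmofs_model()].
#' @param X m x n pattern matrix.
#' @param T m x K one-hot target matrix.
#' @param lambda penalty weight (>= 0).
#' @param alpha elastic-net mix.
#' @return scalar cost `J >= 0`.
#' @export
gmofs_cost <- function(model, X, T, lambda, alpha) {
  O <- forward_full(model, X)$O
  0.5 * sum((T - O)^2) + penalty(model$beta, lambda, alpha)
}

#' Analytic gradients of the training cost
#'
#' Backpropagation with sigmoid output delta
#' `delta_j = (o_j - t_j) o_j (1 - o_j)`. The lasso subgradient at
#' `beta_i = 0` is taken as 0, keeping inactive features inactive.
#'
#' @inheritParams gmofs_cost
#' @return list with `beta`, `V`, `W` gradient arrays matching the model.
#' @export
gmofs_gradients <- function(model, X, T, lambda, alpha) {
  fw <- forward_full(model, X)
  H <- model$p - 1L
  D <- (fw$O - T) * fw$O * (1 - fw$O)                  # m x K output deltas
  gW <- t(fw$Y) %*% D                                  # p x K
  E <- (D %*% t(model$W[seq_len(H), , drop = FALSE])) *
    fw$Yh * (1 - fw$Yh)                                # m x H hidden deltas
  gV <- t(fw$Zaug) %*% E                               # (n+1) x H
  M <- E %*% t(model$V[seq_len(model$n), , drop = FALSE])  # m x n
  gBeta <- colSums(X * M) +
    lambda * (2 * alpha * model$beta + (1 - alpha) * sign(model$beta))
  list(beta = gBeta, V = gV, W = gW)
}

#' One-hot targets for a label vector
#'
#' @param labels class labels.
#' @param levels class ordering (defaults to sorted unique labels).
#' @param lo,hi encoding values for absent/present class.
#' @return m x K target matrix with class levels as column names.
#' @export
one_hot_targets <- function(labels, levels = sort(unique(labels)),
                            lo = 0.05, hi = 0.95) {
  T <- matrix(lo, length(labels), length(levels),
              dimnames = list(NULL, levels))
  T[cbind(seq_along(labels), match(as.character(labels), levels))] <- hi
  T
}

pack <- function(model) c(model$beta, model$V, model$W)

unpack <- function(theta, n, p, K) {
  H <- p - 1L
  gmofs_model(theta[seq_len(n)],
              matrix(theta[n + seq_len((n + 1) * H)], n + 1L, H),
              matrix(theta[n + (n + 1) * H + seq_len(p * K)], p, K))
}

init_model <- function(n, p, K, a, b, seed) {
  with_seed(seed, {
    beta <- stats::runif(n, 0.4, 0.6)
    V <- matrix(stats::runif((n + 1) * (p - 1), -0.1 * b, 0.1 * b), n + 1, p - 1)
    W <- matrix(stats::runif(p * K, -0.1 * a, 0.1 * a), p, K)
    gmofs_model(beta, V, W)
  })
}

#' Train the constrained MLP for one lambda
#'
#' Minimizes the penalized cost subject to the box constraints
#' `0 <= beta_i <= 1`, `|w| <= a`, `|v| <= b` with a bound-constrained
#' quasi-Newton method (L-BFGS-B) driven by the analytic gradients.
#' Initialization is seeded: `beta ~ U[0.4, 0.6]`, weights uniform in
#' `+/- 0.1 *` their bound. If the optimizer fails to decrease the cost the
#' initial model is returned with `converged = FALSE`.
#'
#' @param X m x n normalized pattern matrix.
#' @param T m x K one-hot target matrix.
#' @param lambda penalty weight.
#' @param config a [gmofs_config()].
#' @param seed optional seed overriding `config$seed` for initialization.
#' @param init optional [gmofs_model()] to start from (warm start); when
#'   given, the seeded random init is skipped.
#' @return a [gmofs_model()] with attributes `cost`, `initial_cost`,
#'   `converged`.
#' @export
train_constrained <- function(X, T, lambda, config, seed = config$seed,
                              init = NULL) {
  n <- ncol(X); p <- config$hidden_nodes; K <- ncol(T)
  a <- config$weight_bound_a; b <- config$weight_bound_b
  m0 <- init %||% init_model(n, p, K, a, b, seed)
  H <- p - 1L
  lower <- c(rep(0, n), rep(-b, (n + 1) * H), rep(-a, p * K))
  upper <- c(rep(1, n), rep(b, (n + 1) * H), rep(a, p * K))
  fn <- function(th) gmofs_cost(unpack(th, n, p, K), X, T, lambda, config$alpha)
  gr <- function(th) {
    g <- gmofs_gradients(unpack(th, n, p, K), X, T, lambda, config$alpha)
    c(g$beta, g$V, g$W)
  }
  j0 <- fn(pack(m0))
  fit <- tryCatch(
    stats::optim(pack(m0), fn, gr, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 # tol_fun maps to L-BFGS-B's relative criterion (0.001 ->
                 # factr 1e7, the stock default); MaxIter is the real budget
                 control = list(maxit = config$max_iter,
                                factr = config$tol_fun * 1e10)),
    error = function(e) NULL)
  if (is.null(fit) || fit$value > j0) {
    out <- m0
    attr(out, "cost") <- j0
    attr(out, "converged") <- FALSE
  } else {
    out <- unpack(fit$par, n, p, K)
    attr(out, "cost") <- fit$value
    attr(out, "converged") <- TRUE
  }
  attr(out, "initial_cost") <- j0
  out
}

#' Select significant features by cumulative input weight
#'
#' Sorts `beta` in descending order (ties broken by lower original index)
#' and returns the smallest prefix whose share of `sum(beta)` reaches the
#' threshold `theta`.
#'
#' @param beta non-negative input multipliers, not all zero.
#' @param theta cumulative fraction in `(0, 1]` (default 0.95).
#' @return integer vector of selected feature indices, in descending-beta
#'   order.
#' @export
select_significant <- function(beta, theta = 0.95) {
  if (any(beta < 0)) stop_config("beta must be non-negative")
  if (sum(beta) <= 0) stop_config("all-zero beta: no signal to rank")
  ord <- order(-beta, seq_along(beta))
  frac <- cumsum(beta[ord]) / sum(beta)
  r <- which(frac >= theta - 1e-12)[1]
  ord[seq_len(r)]
}

#' Run GMOFS over the lambda grid
#'
#' For every lambda in the grid: train the constrained MLP (Step 1), select
#' the significant subset from the sorted input multipliers (Step 2), and
#' collect the subsets into a population (Step 3). Each distinct subset is
#' then scored by the evaluator (Step 4: `f1` = subset size, `f2` =
#' cross-validated error of a classifier trained on the subset), and the
#' non-dominated records form the Pareto set/front (Step 5).
#'
#' @param table a normalized [feature_table()] (raw tables are normalized
#'   in place with a note).
#' @param config a [gmofs_config()].
#' @param evaluator function(subset_indices) -> error fraction in `[0, 1]`.
#'   Defaults to 10-fold cross-validation of the unpenalized constrained-MLP
#'   classifier on the masked columns; pass e.g. an LDA-based evaluator (see
#'   [make_subset_evaluator()]) to trade fidelity for speed.
#' @return an object of class `gmofs_result`: `records` (per-lambda
#'   data.frame), `betas` (lambda x feature matrix), `subsets` (list),
#'   `pareto` (a [pareto_archive()] of the non-dominated `(f1, f2)` points,
#'   payloads carrying lambda and subset).
#' @export
run_gmofs <- function(table, config = gmofs_config(), evaluator = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$normalized) table <- normalize_table(table)
  X <- table$values
  T <- one_hot_targets(table$labels, lo = config$target_lo, hi = config$target_hi)
  if (is.null(evaluator))
    evaluator <- make_subset_evaluator(table, classifier = "mlp",
                                       folds = 10, seed = config$seed)
  grid <- config$lambda_grid
  n <- ncol(X)
  betas <- matrix(NA_real_, length(grid), n,
                  dimnames = list(NULL, colnames(X)))
  subsets <- vector("list", length(grid))
  converged <- logical(length(grid))
  prev <- NULL
  for (k in seq_along(grid)) {
    model <- train_constrained(X, T, grid[k], config,
                               seed = spawn_seed(config$seed, paste0("lam", k)),
                               init = if (config$warm_start) prev)
    if (config$warm_start) prev <- model
    betas[k, ] <- model$beta
    # a large-lambda training can shrink every beta to exactly 0; that
    # record carries an empty subset and is flagged out of the Pareto step
    subsets[[k]] <- if (sum(model$beta) > 0)
      select_significant(model$beta, config$threshold) else integer(0)
    converged[k] <- attr(model, "converged")
  }
  # Step 4: score each distinct subset once (memoized)
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = ","), "")
  f2 <- rep(NA_real_, length(grid))
  flagged <- logical(length(grid))
  for (key in unique(keys)) {
    idx <- which(keys == key)
    err <- if (length(subsets[[idx[1]]]) == 0) NA_real_ else
      tryCatch(evaluator(subsets[[idx[1]]]), error = function(e) NA_real_)
    f2[idx] <- err
    flagged[idx] <- is.na(err)
  }
  records <- data.frame(lambda = grid,
                        f1 = lengths(subsets), f2 = f2,
                        converged = converged, flagged = flagged)
  ok <- !flagged
  arch <- pareto_archive(cbind(f1 = records$f1[ok], f2 = records$f2[ok]),
                         lapply(which(ok), function(k)
                           list(lambda = grid[k], subset = subsets[[k]])))
  structure(list(records = records, betas = betas, subsets = subsets,
                 pareto = extract_pareto(arch), config = config),
            class = "gmofs_result")
}

#' @export
print.gmofs_result <- function(x, ...) {
  cat(sprintf("gmofs_result: %d lambda values, subset sizes %d..%d, %d Pareto points\n",
              nrow(x$records), min(x$records$f1), max(x$records$f1),
              x$pareto$np))
  invisible(x)
}
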
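#' Classifier specifications
#'
#' Uniform fit/predict wrappers around the classifiers used for subset
#' evaluation and pipeline assessment: `"lda"` and `"qda"` (MASS) and
#' `"mlp"`, the package's own bound-constrained single-hidden-layer
#' perceptron trained unpenalized (`lambda = 0`). Classifiers are
#' evaluation plumbing consumed through this contract; kernel support-vector
#' machines and decision trees are not available in this build.
#'
#' @param name one of `"lda"`, `"qda"`, `"mlp"`.
#' @param hidden_nodes MLP hidden nodes p including the bias node; the
#'   reference grid searched p over \{3,4,5,6,8,10,15,20\}.
#' @param max_iter MLP training iterations.
#' @param seed MLP initialization seed.
#' @return list with `name`, `fit(X, y)` and `predict(model, X)`.
#' @export
classifier_spec <- function(name = c("lda", "qda", "mlp"),
                            hidden_nodes = 5L, max_iter = 100L, seed = 1L) {
  name <- match.arg(name)
  switch(name,
    lda = list(name = "lda",
               fit = function(X, y) MASS::lda(X, grouping = factor(y)),
               predict = function(model, X)
                 as.character(stats::predict(model, X)$class)),
    qda = list(name = "qda",
               fit = function(X, y) MASS::qda(X, grouping = factor(y)),
               predict = function(model, X)
                 as.character(stats::predict(model, X)$class)),
    mlp = list(name = "mlp",
               fit = function(X, y) {
                 lv <- sort(unique(as.character(y)))
                 cfg <- gmofs_config(hidden_nodes = hidden_nodes,
                                     lambda_grid = 0, max_iter = max_iter,
                                     seed = seed)
                 model <- train_constrained(X, one_hot_targets(y, lv), 0, cfg)
                 list(model = model, levels = lv)
               },
               predict = function(model, X) {
                 O <- gmofs_forward(model$model, X)
                 if (!is.matrix(O)) O <- matrix(O, nrow = 1)
                 model$levels[max.col(O, ties.method = "first")]
               }))
}

#' Cross-validation scheme
#'
#' Random c-fold (each pattern tested exactly once, fold assignment fixed by
#' the seed) or leave-one-sequence-out (each distinct sequence id is one
#' fold).
#'
#' @param kind `"random_kfold"` or `"leave_one_sequence_out"`.
#' @param folds number of folds c (random scheme, >= 2).
#' @param sequence_ids per-pattern sequence labels (sequence scheme).
#' @param seed fold-assignment seed.
#' @return an object of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("random_kfold", "leave_one_sequence_out"),
                      folds = 10L, sequence_ids = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "random_kfold" && folds < 2) stop_config("need >= 2 folds")
  if (kind == "leave_one_sequence_out" && is.null(sequence_ids))
    stop_config("sequence scheme needs sequence_ids")
  structure(list(kind = kind, folds = as.integer(folds),
                 sequence_ids = sequence_ids, seed = as.integer(seed)),
            class = "cv_scheme")
}

fold_assignment <- function(scheme, m) {
  if (scheme$kind == "leave_one_sequence_out") {
    ids <- as.character(scheme$sequence_ids)
    if (length(ids) != m) stop_config("sequence_ids length must equal m")
    return(match(ids, unique(ids)))
  }
  with_seed(scheme$seed, sample(rep_len(seq_len(scheme$folds), m)))
}

#' Mean cross-validated classification error
#'
#' Trains the classifier on c - 1 folds and tests on the held-out fold,
#' repeating for every fold; returns the mean misclassification fraction.
#' Folds whose training split lacks a class, or where fitting fails (e.g. a
#' within-class-constant column for a discriminant classifier), fall back to
#' majority-class prediction and are flagged. With
#' `normalize_scope = "train_only"` the column standardization is fitted on
#' each training split and applied to its test split (leakage-free); with
#' `"global"` the table is standardized once up front; `"none"` uses the
#' values as given.
#'
#' @param table a [feature_table()].
#' @param classifier a [classifier_spec()] (or its name).
#' @param scheme a [cv_scheme()].
#' @param normalize_scope `"none"`, `"train_only"` or `"global"`.
#' @return scalar mean error with attributes `per_fold` and `flagged`.
#' @export
crossval_error <- function(table, classifier = classifier_spec("lda"),
                           scheme = cv_scheme(), normalize_scope = "none") {
  if (is.character(classifier)) classifier <- classifier_spec(classifier)
  if (length(unique(table$labels)) < 2)
    stop_config("cross-validation needs >= 2 classes")
  if (normalize_scope == "global") table <- normalize_table(table)
  X <- table$values
  y <- table$labels
  fold <- fold_assignment(scheme, nrow(X))
  nf <- max(fold)
  per_fold <- numeric(nf)
  flagged <- logical(nf)
  for (f in seq_len(nf)) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (normalize_scope == "train_only") {
      ntab <- normalize_table(feature_table(Xtr, y[tr]))
      Xtr <- ntab$values
      Xte <- apply_normalization(ntab, feature_table(Xte, y[te]))$values
    }
    pred <- tryCatch({
      if (length(unique(y[tr])) < length(unique(y))) stop("class missing in fold")
      fit <- classifier$fit(Xtr, y[tr])
      classifier$predict(fit, Xte)
    }, error = function(e) {
      flagged[f] <<- TRUE
      rep(names(which.max(base::table(y[tr]))), sum(te))
    })
    per_fold[f] <- mean(pred != y[te])
  }
  structure(mean(per_fold), per_fold = per_fold, flagged = flagged)
}

#' Memoized feature-subset evaluator
#'
#' Returns a closure mapping a set of column indices to the mean c-fold
#' cross-validation error of `classifier` trained on those columns, with the
#' fold assignment fixed once by the seed (so all subsets in one run are
#' compared on identical folds) and results cached per subset.
#'
#' @param table a [feature_table()].
#' @param classifier classifier name or [classifier_spec()].
#' @param folds number of folds c (default 10).
#' @param seed fold-assignment seed.
#' @return function(subset_indices) -> error fraction; the environment
#'   carries `n_calls()` (logical evaluations, cache hits included) and
#'   `n_trainings()` (distinct subsets actually trained).
#' @export
make_subset_evaluator <- function(table, classifier = "lda", folds = 10L,
                                  seed = 1L) {
  if (is.character(classifier)) classifier <- classifier_spec(classifier)
  scheme <- cv_scheme("random_kfold", folds = folds, seed = seed)
  cache <- new.env(parent = emptyenv())
  calls <- 0L
  f <- function(subset) {
    calls <<- calls + 1L
    subset <- sort(unique(as.integer(subset)))
    if (!length(subset)) stop_config("empty subset")
    key <- paste(subset, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    sub <- feature_table(table$values[, subset, drop = FALSE], table$labels)
    err <- as.numeric(crossval_error(sub, classifier, scheme))
    cache[[key]] <- err
    err
  }
  attr(f, "n_calls") <- function() calls
  attr(f, "n_trainings") <- function() length(ls(cache))
  f
}

#' Majority-voting-filter configuration
#'
#' The filter smooths a stream of classified gait modes by replacing each
#' label with the most frequent label in a window of `2q + 1` consecutive
#' classifications.
#'
#' @param q half-window (>= 0): `q` previous, the current and `q` subsequent
#'   classifications.
#' @return an object of class `mvf_config` with the derived `window_length`.
#' @export
mvf_config <- function(q) {
  if (q < 0 || q != round(q)) stop_config("q must be a non-negative integer")
  structure(list(q = as.integer(q), window_length = 2L * as.integer(q) + 1L),
            class = "mvf_config")
}

#' Majority-vote label smoothing
#'
#' Output `i` is the most frequent label among positions `i - q .. i + q`
#' (the window shrinks at the stream edges). Ties are broken by the previous
#' filtered output when it is among the tied leaders (the raw label at the
#' stream start), otherwise by the tied leader occurring latest in the
#' window. Output length equals input length. Using `q` subsequent values
#' implies a deployment delay of `q` output periods, which
#' [realtime_feasible()] accounts for.
#'
#' @param stream character vector of classified modes (time-ordered).
#' @param config an [mvf_config()] (or an integer q).
#' @return filtered label vector with attribute `window_length`.
#' @export
majority_vote_filter <- function(stream, config) {
  if (!inherits(config, "mvf_config")) config <- mvf_config(config)
  q <- config$q
  n <- length(stream)
  if (n == 0) stop_config("empty label stream")
  out <- character(n)
  prev <- stream[1]
  for (i in seq_len(n)) {
    w <- stream[max(1, i - q):min(n, i + q)]
    tab <- table(w)
    leaders <- names(tab)[tab == max(tab)]
    if (length(leaders) == 1L) out[i] <- leaders
    else if (prev %in% leaders) out[i] <- prev
    else out[i] <- leaders[which.max(vapply(leaders, function(l)
      max(which(w == l)), 0))]
    prev <- out[i]
  }
  structure(out, window_length = config$window_length)
}

#' Real-time feasibility of a windowing + filter configuration
#'
#' The user must experience the prosthesis as responsive: the decision delay
#' introduced by waiting for `q` subsequent classifications must stay within
#' the 300 ms intent-to-motion budget. The delay is `q * Lf` ms under
#' disjoint windowing and `q * I` ms under overlapped windowing.
#'
#' @param windowing a [windowing_config()].
#' @param mvf an [mvf_config()].
#' @param budget_ms latency budget (default 300 ms).
#' @return list with `feasible`, `delay_ms`, `budget_ms` and a `report`
#'   string.
#' @export
realtime_feasible <- function(windowing, mvf, budget_ms = 300) {
  stopifnot(inherits(windowing, "windowing_config"))
  if (!inherits(mvf, "mvf_config")) mvf <- mvf_config(mvf)
  step <- if (windowing$mode == "disjoint") windowing$frame_ms
          else windowing$increment_ms
  delay <- mvf$q * step
  list(feasible = delay <= budget_ms, delay_ms = delay, budget_ms = budget_ms,
       report = sprintf("MVF delay q * %s = %d * %g = %g ms (budget %g ms): %s",
                        if (windowing$mode == "disjoint") "Lf" else "I",
                        mvf$q, step, delay, budget_ms,
                        if (delay <= budget_ms) "feasible" else "infeasible"))
}

#' Paired Wilcoxon signed-rank comparison of per-fold accuracies
#'
#' Reporting helper wrapping [stats::wilcox.test()] for comparing two
#' classifiers' per-fold results.
#'
#' @param errors_a,errors_b paired per-fold error vectors.
#' @param level significance level.
#' @return list with `p_value`, `significant`, `better` ("a", "b" or "tie").
#' @export
compare_classifiers <- function(errors_a, errors_b, level = 0.05) {
  wt <- suppressWarnings(stats::wilcox.test(errors_a, errors_b, paired = TRUE))
  sig <- is.finite(wt$p.value) && wt$p.value < level
  list(p_value = wt$p.value, significant = sig,
       better = if (!sig) "tie" else if (mean(errors_a) < mean(errors_b)) "a" else "b")
}
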
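#' Multi-objective BBO configuration
#'
#' Biogeography-based optimization over binary feature masks, minimizing
#' `(f1, f2)` = (subset size, c-fold cross-validation error). Defaults
#' follow the reference tuning: mutation rate 0.04, 2 elites, population
#' 100, 1000 generations, sinusoidal migration model, 10 CV folds.
#'
#' @param variant `"VEBBO"`, `"NSBBO"`, `"NPBBO"` or `"SPBBO"` (vector
#'   evaluated, non-dominated sorting, niched Pareto, strength Pareto).
#' @param dimension number of features d (mask length).
#' @param pop_size population size N.
#' @param generations generation limit Gen.
#' @param mutation_rate per-bit mutation probability mu.
#' @param elites number of elites E preserved unchanged each generation.
#' @param migration_model `"sinusoidal"` or `"linear"`.
#' @param cv_folds folds c for the objective evaluator.
#' @param sharing_radius niche radius in normalized objective space (NPBBO).
#' @param seed run seed.
#' @return an object of class `bbo_config`.
#' @export
bbo_config <- function(variant = c("NSBBO", "VEBBO", "NPBBO", "SPBBO"),
                       dimension, pop_size = 100L, generations = 1000L,
                       mutation_rate = 0.04, elites = 2L,
                       migration_model = c("sinusoidal", "linear"),
                       cv_folds = 10L, sharing_radius = 0.1, seed = 1L) {
  variant <- match.arg(toupper(variant[1]), c("NSBBO", "VEBBO", "NPBBO", "SPBBO"))
  if (mutation_rate < 0 || mutation_rate > 1) stop_config("mu must be in [0, 1]")
  if (elites < 0 || elites > pop_size) stop_config("need 0 <= E <= N")
  if (dimension < 1) stop_config("dimension must be >= 1")
  if (cv_folds < 2) stop_config("need >= 2 CV folds")
  structure(list(variant = variant, dimension = as.integer(dimension),
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate, elites = as.integer(elites),
                 migration_model = match.arg(migration_model),
                 cv_folds = as.integer(cv_folds),
                 sharing_radius = sharing_radius, seed = as.integer(seed)),
            class = "bbo_config")
}

#' Immigration and emigration rates by fitness rank
#'
#' With the population sorted by the variant's scalar fitness (best at rank
#' 1), the sinusoidal model assigns rank k immigration
#' `(cos(pi (N - k) / N) + 1) / 2` and emigration `(cos(pi k / N) + 1) / 2`,
#' which sum to 1 at every rank; the linear model uses `k / N` and
#' `1 - k / N`. Good habitats (low rank) emigrate features, poor habitats
#' immigrate them.
#'
#' @param rank rank vector in `1..N` (1 = best).
#' @param N population size.
#' @param model `"sinusoidal"` or `"linear"`.
#' @return list with numeric vectors `immigration` and `emigration`.
#' @export
migration_rates <- function(rank, N, model = c("sinusoidal", "linear")) {
  model <- match.arg(model)
  if (any(rank < 1 | rank > N)) stop_config("ranks must lie in 1..N")
  if (model == "sinusoidal") {
    list(immigration = (cos(pi * (N - rank) / N) + 1) / 2,
         emigration = (cos(pi * rank / N) + 1) / 2)
  } else {
    list(immigration = rank / N, emigration = 1 - rank / N)
  }
}

#' Evaluate a binary mask
#'
#' `f1` is the popcount of the mask; `f2` the mean c-fold CV
#' misclassification fraction of the classifier trained on the masked
#' columns (via the evaluator closure). An all-zero mask is repaired before
#' evaluation by setting one uniformly random bit (f2 is undefined with no
#' features; repair is the standard fix in binary subset EAs).
#'
#' @param mask 0/1 vector of length d.
#' @param evaluator function(subset_indices) -> error fraction, e.g. from
#'   [make_subset_evaluator()].
#' @return list with `mask` (possibly repaired), `f1`, `f2`.
#' @export
evaluate_mask <- function(mask, evaluator) {
  if (sum(mask) == 0) mask[sample.int(length(mask), 1)] <- 1L
  list(mask = mask, f1 = sum(mask), f2 = evaluator(which(mask == 1)))
}

# fast non-dominated sorting: front rank per row of the objectives matrix
nondominated_rank <- function(obj) {
  n <- nrow(obj)
  rank <- integer(n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    sub <- obj[remaining, , drop = FALSE]
    nd <- vapply(seq_along(remaining), function(i)
      !any(vapply(seq_along(remaining), function(j)
        j != i && dominates(sub[j, ], sub[i, ]), logical(1))),
      logical(1))
    rank[remaining[nd]] <- r
    remaining <- remaining[!nd]
  }
  rank
}

crowding_distance <- function(obj) {
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  cd <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    o <- order(obj[, k])
    rng <- obj[o[n], k] - obj[o[1], k]
    cd[o[c(1, n)]] <- Inf
    if (rng > 0)
      cd[o[2:(n - 1)]] <- cd[o[2:(n - 1)]] +
        (obj[o[3:n], k] - obj[o[1:(n - 2)], k]) / rng
  }
  cd
}

# normalized objectives for distance-based computations: f1/d in [0,1], f2 raw
normalize_objectives <- function(obj, d) cbind(obj[, 1] / d, obj[, 2])

niche_count <- function(obj_norm, radius) {
  dmat <- as.matrix(stats::dist(obj_norm))
  sh <- 1 - (dmat / radius)^2
  sh[sh < 0] <- 0
  rowSums(sh)
}

# order of the population, best first, under the variant's scalar fitness
rank_order <- function(obj, config, state) {
  N <- nrow(obj)
  d <- config$dimension
  switch(config$variant,
    NSBBO = {
      nr <- nondominated_rank(obj)
      cd <- numeric(N)
      for (r in unique(nr))
        cd[nr == r] <- crowding_distance(obj[nr == r, , drop = FALSE])
      order(nr, -cd)
    },
    VEBBO = {
      # population split evenly across the two objectives, reshuffled each
      # generation; each subpopulation ranks by its own single objective and
      # the global order interleaves the subpopulation ranks
      sub <- state$vebbo_split
      key <- integer(N)
      for (s in 1:2) {
        idx <- which(sub == s)
        key[idx][order(obj[idx, s])] <- seq_along(idx)
      }
      order(key, sub)
    },
    NPBBO = {
      domcnt <- vapply(seq_len(N), function(i)
        sum(vapply(seq_len(N), function(j)
          j != i && dominates(obj[j, ], obj[i, ]), logical(1))), 0)
      nc <- niche_count(normalize_objectives(obj, d), config$sharing_radius)
      order(domcnt, nc)
    },
    SPBBO = {
      arch <- state$spbbo_archive      # matrix of archive objective vectors
      if (is.null(arch) || nrow(arch) == 0) return(order(nondominated_rank(obj)))
      strength <- vapply(seq_len(nrow(arch)), function(a)
        sum(vapply(seq_len(N), function(i)
          dominates(arch[a, ], obj[i, ], weak = TRUE), logical(1))) / (N + 1),
        0)
      fit <- vapply(seq_len(N), function(i)
        1 + sum(strength[vapply(seq_len(nrow(arch)), function(a)
          dominates(arch[a, ], obj[i, ], weak = TRUE), logical(1))]), 0)
      order(fit, nondominated_rank(obj))
    })
}

#' One BBO generation
#'
#' Sorts the population by the variant's scalar fitness, computes per-rank
#' immigration/emigration rates, then for every non-elite individual decides
#' per bit whether to immigrate (with its immigration probability) from a
#' source drawn with probability proportional to emigration rates, applies
#' per-bit mutation at rate mu, and re-evaluates. The E elites are preserved
#' unchanged.
#'
#' @param population list with `masks` (N x d matrix) and `objectives`
#'   (N x 2 matrix), all individuals evaluated.
#' @param config a [bbo_config()].
#' @param evaluator objective evaluator closure.
#' @param state variant state (VEBBO split, SPBBO archive); internal.
#' @return updated population list.
#' @export
generation_step <- function(population, config, evaluator, state = list()) {
  N <- config$pop_size
  d <- config$dimension
  if (is.null(state$vebbo_split))
    state$vebbo_split <- sample(rep_len(1:2, N))
  ord <- rank_order(population$objectives, config, state)
  rates <- migration_rates(seq_len(N), N, config$migration_model)
  masks <- population$masks[ord, , drop = FALSE]
  objectives <- population$objectives[ord, , drop = FALSE]
  new_masks <- masks
  emig <- rates$emigration
  if (sum(emig) <= 0) emig <- rep(1, N)
  for (i in seq_len(N)) {
    if (i <= config$elites) next               # elites preserved unchanged
    bit_imm <- stats::runif(d) < rates$immigration[i]
    if (any(bit_imm)) {
      src <- sample.int(N, sum(bit_imm), replace = TRUE, prob = emig)
      new_masks[i, bit_imm] <- masks[cbind(src, which(bit_imm))]
    }
    flip <- stats::runif(d) < config$mutation_rate
    new_masks[i, flip] <- 1L - new_masks[i, flip]
  }
  new_obj <- objectives
  for (i in seq_len(N)) {
    ev <- evaluate_mask(new_masks[i, ], evaluator)
    new_masks[i, ] <- ev$mask
    new_obj[i, ] <- c(ev$f1, ev$f2)
  }
  list(masks = new_masks, objectives = new_obj, state = state)
}

update_archive <- function(arch_obj, arch_masks, obj, masks) {
  all_obj <- rbind(arch_obj, obj)
  all_masks <- rbind(arch_masks, masks)
  dup <- duplicated(all_masks)
  all_obj <- all_obj[!dup, , drop = FALSE]
  all_masks <- all_masks[!dup, , drop = FALSE]
  keep <- vapply(seq_len(nrow(all_obj)), function(i)
    !any(vapply(seq_len(nrow(all_obj)), function(j)
      j != i && dominates(all_obj[j, ], all_obj[i, ]), logical(1))),
    logical(1))
  list(obj = all_obj[keep, , drop = FALSE],
       masks = all_masks[keep, , drop = FALSE])
}

#' Run multi-objective BBO
#'
#' Evolves a seeded random population of binary feature masks for `Gen`
#' generations under the selected variant, maintaining an external
#' non-dominated archive over every evaluated individual. Logical objective
#' evaluations total `N * Gen` across generations plus `N` for the initial
#' population (cache hits included; repeated masks are not retrained).
#'
#' @param config a [bbo_config()].
#' @param evaluator objective evaluator closure from
#'   [make_subset_evaluator()] (or any function(subset) -> error).
#' @return an object of class `mobbo_result`: `archive` (a
#'   [pareto_archive()] whose payloads are the feature masks), `counts`
#'   (`n_initial`, `n_generation_evals`, `n_total`), `config`.
#' @export
run_mobbo <- function(config, evaluator) {
  N <- config$pop_size; d <- config$dimension
  with_seed(config$seed, {
    masks <- matrix(as.integer(stats::runif(N * d) < 0.5), N, d)
    obj <- matrix(0, N, 2, dimnames = list(NULL, c("f1", "f2")))
    for (i in seq_len(N)) {
      ev <- evaluate_mask(masks[i, ], evaluator)
      masks[i, ] <- ev$mask
      obj[i, ] <- c(ev$f1, ev$f2)
    }
    arch <- update_archive(NULL, NULL, obj, masks)
    state <- list()
    pop <- list(masks = masks, objectives = obj)
    for (g in seq_len(config$generations)) {
      state$vebbo_split <- sample(rep_len(1:2, N))
      if (config$variant == "SPBBO") state$spbbo_archive <- arch$obj
      pop <- generation_step(pop, config, evaluator, state)
      state <- pop$state
      arch <- update_archive(arch$obj, arch$masks, pop$objectives, pop$masks)
    }
    archive <- pareto_archive(arch$obj,
                              lapply(seq_len(nrow(arch$masks)), function(i)
                                list(mask = arch$masks[i, ])))
    structure(list(archive = archive,
                   counts = list(n_initial = N,
                                 n_generation_evals = N * config$generations,
                                 n_total = N * (config$generations + 1L)),
                   config = config),
              class = "mobbo_result")
  })
}

#' @export
print.mobbo_result <- function(x, ...) {
  cat(sprintf("mobbo_result (%s): %d archive points after %d generations (N = %d)\n",
              x$config$variant, x$archive$np, x$config$generations,
              x$config$pop_size))
  cat(sprintf("objective evaluations: %d initial + %d across generations\n",
              x$counts$n_initial, x$counts$n_generation_evals))
  invisible(x)
}
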
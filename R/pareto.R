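#' Pareto dominance (minimization)
#'
#' `a` strictly dominates `b` when `a <= b` in every objective with at least
#' one strict inequality; weak dominance drops the strictness requirement
#' (equal vectors weakly dominate each other).
#'
#' @param a,b numeric objective vectors of equal length.
#' @param weak use weak dominance?
#' @return logical scalar.
#' @export
dominates <- function(a, b, weak = FALSE) {
  if (length(a) != length(b)) stop_config("objective vectors differ in length")
  if (weak) all(a <= b) else all(a <= b) && any(a < b)
}

#' Pareto archive
#'
#' A collection of points, each an objective vector (minimization) plus an
#' opaque payload (a feature mask, a lambda value, ...).
#'
#' @param objectives numeric matrix, one row per point, or a list of vectors.
#' @param payloads optional list of payloads, one per point.
#' @return an object of class `pareto_archive`.
#' @export
pareto_archive <- function(objectives, payloads = NULL) {
  if (is.list(objectives) && !is.data.frame(objectives))
    objectives <- do.call(rbind, objectives)
  objectives <- as.matrix(objectives)
  if (!all(is.finite(objectives))) stop_config("objectives must be finite")
  if (is.null(payloads)) payloads <- vector("list", nrow(objectives))
  if (length(payloads) != nrow(objectives))
    stop_config("one payload per point required")
  structure(list(objectives = objectives, payloads = payloads,
                 np = nrow(objectives)),
            class = "pareto_archive")
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat(sprintf("pareto_archive: %d points, %d objectives\n",
              x$np, ncol(x$objectives)))
  invisible(x)
}

#' Extract the non-dominated subset of a point set
#'
#' Returns exactly the points not strictly dominated by any other point.
#' Duplicate objective vectors are all retained (their payloads may differ).
#'
#' @param points a [pareto_archive()] or an objectives matrix.
#' @return a `pareto_archive` flagged as a front.
#' @export
extract_pareto <- function(points) {
  if (!inherits(points, "pareto_archive")) points <- pareto_archive(points)
  if (points$np == 0) stop_config("empty point set")
  obj <- points$objectives
  keep <- vapply(seq_len(nrow(obj)), function(i) {
    !any(vapply(seq_len(nrow(obj)), function(j)
      j != i && dominates(obj[j, ], obj[i, ]), logical(1)))
  }, logical(1))
  out <- pareto_archive(obj[keep, , drop = FALSE], points$payloads[keep])
  attr(out, "is_front") <- TRUE
  out
}

#' Normalized hypervolume of a Pareto front
#'
#' The front-quality score used throughout this package: the mean over front
#' points of the product of their objective values,
#' `sum_j prod_i f_ji / Np`. Smaller is better. Note this is NOT the
#' standard dominated-hypervolume indicator; see [dominated_hypervolume()]
#' for that.
#'
#' @param front a [pareto_archive()] with at least one point.
#' @return scalar score (smaller is better).
#' @export
normalized_hypervolume <- function(front) {
  if (!inherits(front, "pareto_archive")) front <- pareto_archive(front)
  if (front$np < 1) stop_config("empty front")
  mean(apply(front$objectives, 1, prod))
}

#' Standard dominated hypervolume (2 objectives)
#'
#' The conventional hypervolume indicator: Lebesgue measure of the region
#' dominated by the front and bounded by a reference point (larger is
#' better). Provided for users familiar with the standard indicator; it is
#' distinct from [normalized_hypervolume()], the metric used for front
#' comparison here.
#'
#' @param front a [pareto_archive()] with 2-objective points.
#' @param ref reference point (componentwise upper bound).
#' @return scalar dominated volume (larger is better).
#' @export
dominated_hypervolume <- function(front, ref) {
  if (!inherits(front, "pareto_archive")) front <- pareto_archive(front)
  obj <- front$objectives
  if (ncol(obj) != 2) stop_config("dominated_hypervolume supports 2 objectives")
  obj <- obj[obj[, 1] <= ref[1] & obj[, 2] <= ref[2], , drop = FALSE]
  if (nrow(obj) == 0) return(0)
  obj <- extract_pareto(obj)$objectives
  obj <- unique(obj[order(obj[, 1], obj[, 2]), , drop = FALSE])
  prev_f2 <- ref[2]
  vol <- 0
  for (i in seq_len(nrow(obj))) {
    vol <- vol + (ref[1] - obj[i, 1]) * (prev_f2 - obj[i, 2])
    prev_f2 <- obj[i, 2]
  }
  vol
}

#' Relative coverage of one front by another
#'
#' Percentage of the points of `a` weakly dominated by at least one point of
#' `b`. By weak dominance, `relative_coverage(a, a)` is 100.
#'
#' @param a,b non-empty [pareto_archive()]s.
#' @return percentage in `[0, 100]`.
#' @export
relative_coverage <- function(a, b) {
  if (!inherits(a, "pareto_archive")) a <- pareto_archive(a)
  if (!inherits(b, "pareto_archive")) b <- pareto_archive(b)
  if (a$np == 0 || b$np == 0) stop_config("both fronts must be non-empty")
  covered <- vapply(seq_len(a$np), function(i)
    any(vapply(seq_len(b$np), function(j)
      dominates(b$objectives[j, ], a$objectives[i, ], weak = TRUE),
      logical(1))),
    logical(1))
  100 * mean(covered)
}

#' Coverage matrix for a set of named fronts
#'
#' Entry in column i, row j is the percentage of front i's points weakly
#' dominated by at least one point of front j (diagonal left NA).
#'
#' @param archives named list of [pareto_archive()]s.
#' @return square numeric matrix with a `Mean RC (%)` summary row.
#' @export
coverage_matrix <- function(archives) {
  nm <- names(archives)
  m <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in nm) for (j in nm) if (i != j)
    m[j, i] <- relative_coverage(archives[[i]], archives[[j]])
  rbind(m, `Mean RC (%)` = colMeans(m, na.rm = TRUE))
}

#' Combine several fronts into one
#'
#' Pools the points of all archives, applies the non-dominated filter, and
#' counts each source's contribution to the combined front. Points with
#' duplicate objective vectors are credited to every source holding them.
#'
#' @param archives named list of [pareto_archive()]s.
#' @return list with `combined` (a `pareto_archive`) and `contributions`
#'   (named integer vector).
#' @export
combine_fronts <- function(archives) {
  if (!length(archives)) stop_config("need at least one archive")
  nm <- names(archives) %||% paste0("front", seq_along(archives))
  obj <- do.call(rbind, lapply(archives, function(a) a$objectives))
  src <- rep(nm, vapply(archives, function(a) a$np, 0L))
  pay <- do.call(c, lapply(archives, function(a) a$payloads))
  combined <- extract_pareto(pareto_archive(obj, as.list(seq_len(nrow(obj)))))
  kept <- unlist(combined$payloads)
  kept_obj <- unique(combined$objectives)
  contrib <- stats::setNames(integer(length(nm)), nm)
  for (s in nm) {
    s_obj <- obj[src == s, , drop = FALSE]
    # a source is credited for every distinct combined-front vector it holds
    contrib[s] <- sum(vapply(seq_len(nrow(kept_obj)), function(k)
      any(apply(s_obj, 1, function(r) all(r == kept_obj[k, ]))), logical(1)))
  }
  list(combined = pareto_archive(combined$objectives, pay[kept]),
       contributions = contrib)
}
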
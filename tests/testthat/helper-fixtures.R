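# shared fixtures and independent oracles (all built in code, no data files)

# a small labeled recording: k seconds at fs Hz, 3 channels of white noise,
# labels switching halfway
tiny_recording <- function(seconds = 2, fs = 100, seed = 1) {
  n <- round(seconds * fs)
  set.seed(seed)
  raw_recording(matrix(rnorm(3 * n), n, 3,
                       dimnames = list(NULL, c("a", "b", "c"))),
                fs = fs,
                labels = rep(c("NW", "SW"), each = ceiling(n / 2))[1:n])
}

# O(n^2) all-pairs non-dominated filter (independent of extract_pareto)
brute_pareto_keep <- function(obj) {
  n <- nrow(obj)
  vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      if (j == i) return(FALSE)
      all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])
    }, logical(1)))
  }, logical(1))
}

# double-loop weak-dominance coverage of A by B, in percent
brute_coverage <- function(A, B) {
  cov <- 0
  for (i in seq_len(nrow(A))) {
    hit <- FALSE
    for (j in seq_len(nrow(B))) if (all(B[j, ] <= A[i, ])) { hit <- TRUE; break }
    cov <- cov + hit
  }
  100 * cov / nrow(A)
}

# exhaustive objective evaluation of all non-empty masks of d features
exhaustive_front <- function(d, evaluator) {
  masks <- as.matrix(expand.grid(rep(list(0:1), d)))[-1, , drop = FALSE]
  obj <- t(apply(masks, 1, function(m)
    c(sum(m), evaluator(which(m == 1)))))
  obj[brute_pareto_keep(obj), , drop = FALSE]
}

# objective-vector membership of each row of `a` in rows of `b`
rows_in <- function(a, b) {
  keyb <- apply(round(b, 10), 1, paste, collapse = "|")
  apply(round(a, 10), 1, paste, collapse = "|") %in% keyb
}

# separable planted table used across modules
separable_table <- function(m = 120, n = 8, informative = 1:2, classes = 2,
                            effect = 6, seed = 11) {
  generate_planted_table(planted_table_config(
    m = m, n = n, informative = informative, classes = classes,
    effect_size = effect, seed = seed))
}
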
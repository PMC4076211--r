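#' Compare two sets of dimension estimates
#'
#' Reports the two medians (standard midpoint rule, so even counts give
#' half-integer medians for integer data) and a two-sided Wilcoxon
#' rank-sum p-value. For small samples the p-value is computed by exact
#' enumeration of all rank assignments (midranks under ties), so it
#' remains exact in the presence of ties; for larger samples the normal
#' approximation with tie correction is used.
#'
#' @param values_a,values_b numeric vectors; `NA`s are dropped.
#' @param exact_limit enumeration is used while
#'   `choose(n_a + n_b, n_a) <= exact_limit` (default 20000).
#' @return list with `median_a`, `median_b`, `p_value`, `n_a`, `n_b`,
#'   `computable`. When either set is empty after `NA` removal,
#'   `computable` is `FALSE` and the statistics are `NA`.
#' @export
compare_sets <- function(values_a, values_b, exact_limit = 20000) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) == 0L || length(b) == 0L) {
    return(list(median_a = if (length(a)) stats::median(a) else NA_real_,
                median_b = if (length(b)) stats::median(b) else NA_real_,
                p_value = NA_real_, n_a = length(a), n_b = length(b),
                computable = FALSE))
  }
  p <- if (choose(length(a) + length(b), length(a)) <= exact_limit) {
    rank_sum_exact_p(a, b)
  } else {
    suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = FALSE, correct = TRUE)$p.value)
  }
  list(median_a = stats::median(a), median_b = stats::median(b),
       p_value = p, n_a = length(a), n_b = length(b), computable = TRUE)
}

# exact two-sided rank-sum p-value by enumeration of all assignments of
# the pooled midranks to group A; two-sided via |W - E[W]|
rank_sum_exact_p <- function(a, b) {
  n_a <- length(a); n <- n_a + length(b)
  r <- rank(c(a, b))                  # midranks
  w_obs <- sum(r[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2
  dev_obs <- abs(w_obs - mu)
  combos <- utils::combn(n, n_a)
  w_all <- colSums(matrix(r[combos], nrow = n_a))
  mean(abs(w_all - mu) >= dev_obs - 1e-9)
}
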
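#' Two-sided Mann-Whitney U test
#'
#' Wraps [stats::wilcox.test()] (exact for small untied samples, normal
#' approximation with tie correction otherwise). The reported statistic is
#' U for the first sample: the number of pairs `(a_i, b_j)` with
#' `a_i > b_j`, counting ties as one half.
#'
#' @param a,b Numeric samples.
#' @return One-row tibble: `statistic`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
mwu_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1L || length(b) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  res <- suppressWarnings(stats::wilcox.test(a, b))
  tibble::tibble(
    statistic = unname(res$statistic),
    p_value = res$p.value,
    n_a = length(a),
    n_b = length(b),
    method = "Mann-Whitney U (two-sided)"
  )
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' The omnibus H comes from [stats::kruskal.test()] (tie-corrected). Dunn's
#' pairwise z statistics are computed from the pooled ranks:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with tie term `T = sum(t^3 - t)` over tied groups. Pairwise p-values are
#' two-sided and unadjusted by default.
#'
#' @param x Numeric values.
#' @param g Group labels (>= 3 groups, each with >= 2 observations).
#' @param p_adjust Adjustment for the pairwise p-values, passed to
#'   [stats::p.adjust()].
#' @return List with `test` (one-row tibble: `statistic`, `df`, `p_value`,
#'   `method`) and `pairwise` (tibble: `group_a`, `group_b`, `z`,
#'   `p_value`, `p_adjusted`, mean ranks and group sizes).
#' @export
kruskal_dunn <- function(x, g, p_adjust = "none") {
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- as.character(g[keep])
  groups <- unique(g)
  if (length(groups) < 3L) stop(">= 3 groups required", call. = FALSE)
  n_by <- table(g)
  if (any(n_by < 2L)) {
    stop("every group needs >= 2 observations", call. = FALSE)
  }
  kw <- stats::kruskal.test(x, factor(g))
  r <- rank(x)
  n_total <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n_total - 1))
  var_core <- n_total * (n_total + 1) / 12 - tie_term
  mean_rank <- tapply(r, g, mean)
  pairs <- utils::combn(sort(groups), 2L, simplify = FALSE)
  pairwise <- purrr::map(pairs, function(p) {
    ni <- n_by[[p[1L]]]; nj <- n_by[[p[2L]]]
    z <- (mean_rank[[p[1L]]] - mean_rank[[p[2L]]]) /
      sqrt(var_core * (1 / ni + 1 / nj))
    tibble::tibble(
      group_a = p[1L], group_b = p[2L],
      mean_rank_a = mean_rank[[p[1L]]], mean_rank_b = mean_rank[[p[2L]]],
      n_a = ni, n_b = nj,
      z = z,
      p_value = 2 * stats::pnorm(-abs(z))
    )
  }) |> dplyr::bind_rows()
  pairwise$p_adjusted <- stats::p.adjust(pairwise$p_value, method = p_adjust)
  list(
    test = tibble::tibble(
      statistic = unname(kw$statistic),
      df = unname(kw$parameter),
      p_value = kw$p.value,
      method = "Kruskal-Wallis rank sum (tie-corrected)"
    ),
    pairwise = pairwise
  )
}

#' Pearson chi-square test on a contingency table
#'
#' No Yates continuity correction (matching per-codon and per-bin count
#' comparisons on large tables); [stats::chisq.test()] warns when an
#' expected count drops below 5.
#'
#' @param tab Matrix of non-negative counts (e.g. 2 x k).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  res <- stats::chisq.test(tab, correct = FALSE)
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    method = "Pearson chi-square (no continuity correction)"
  )
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; p from the t
#' approximation (exact p is unavailable with ties).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return One-row tibble: `estimate` (rho), `p_value`, `n`, `method`;
#'   `NA` estimate when either vector is constant.
#' @export
spearman_test <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop(">= 3 paired observations required", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(tibble::tibble(estimate = NA_real_, p_value = NA_real_,
                          n = length(x), method = "Spearman rank correlation"))
  }
  res <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble::tibble(
    estimate = unname(res$estimate),
    p_value = res$p.value,
    n = length(x),
    method = "Spearman rank correlation"
  )
}

#' Exact two-sided sign test
#'
#' Exact binomial test of `k` successes in `n` paired comparisons under a
#' null success probability of one half; two-sided by doubling the smaller
#' tail, capped at 1. For `k = n` this reduces to `2 * 0.5^n`.
#'
#' @param k Number of comparisons in the favoured direction.
#' @param n Number of comparisons.
#' @return One-row tibble: `statistic` (k), `n`, `p_value`, `method`.
#' @export
#' @examples
#' sign_test(18, 18)  # p = 2 * 0.5^18
sign_test <- function(k, n) {
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (k < 0L || k > n) stop("k must lie in [0, n]", call. = FALSE)
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  tibble::tibble(
    statistic = as.integer(k),
    n = as.integer(n),
    p_value = p,
    method = "exact sign test (two-sided, doubled tail)"
  )
}
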
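#' Kruskal-Wallis comparison of grouped samples
#'
#' Nonparametric one-way comparison of two or more groups (the rank-based
#' extension of the Wilcoxon rank-sum test): the classical F statistic is
#' replaced by a chi-square statistic computed on ranks, with tie
#' correction, testing whether the groups share a common distribution.
#' Used here to compare Gamma parameters and moments across participant
#' groups.
#'
#' @param data A data frame with a grouping column and a value column, e.g.
#'   per-participant NSR values per diagnosis group.
#' @param group,value Column names (defaults `"group"`, `"value"`).
#' @return A one-row tibble: `statistic` (chi-square H), `df`, `p_value`,
#'   `n`, `k` (number of groups).
#' @examples
#' df <- data.frame(
#'   group = rep(c("a", "b"), each = 3),
#'   value = c(1, 2, 3, 101, 102, 103)
#' )
#' kruskal_wallis(df)
#' @export
kruskal_wallis <- function(data, group = "group", value = "value") {
  g <- factor(data[[group]])
  v <- data[[value]]
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) == 0)) stop("every group must be nonempty", call. = FALSE)
  if (length(unique(v)) == 1) {
    # all ranks tied: H is 0 by convention, no evidence of separation
    return(tibble::tibble(
      statistic = 0, df = nlevels(g) - 1, p_value = 1,
      n = length(v), k = nlevels(g)
    ))
  }
  kt <- stats::kruskal.test(v, g)
  tibble::tibble(
    statistic = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value, n = length(v), k = nlevels(g)
  )
}

#' One-dimensional Earth mover's distance
#'
#' Wasserstein-1 distance between two empirical distributions, computed
#' exactly as the integral of the absolute difference of their CDFs over the
#' pooled support. Zero iff the samples coincide as distributions; symmetric
#' and satisfying the triangle inequality.
#'
#' @param a,b Numeric samples.
#' @return Nonnegative distance in the units of the samples.
#' @examples
#' emd_1d(0.2, 0.7) # 0.5
#' @export
emd_1d <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  xs <- sort(unique(c(a, b)))
  if (length(xs) == 1) {
    return(0)
  }
  fa <- stats::ecdf(a)(xs)
  fb <- stats::ecdf(b)(xs)
  dx <- diff(xs)
  sum(abs(fa - fb)[-length(xs)] * dx)
}

#' Pairwise EMD matrix across emotions
#'
#' Symmetric matrix of 1-D Earth mover's distances between the spike
#' amplitude samples of each pair of emotions (or any named sample
#' collection), zero diagonal.
#'
#' @param samples Named list of numeric samples (e.g. pooled MMS amplitudes
#'   per emotion).
#' @param min_n Minimum sample size per entry (default 5); smaller samples
#'   produce `NA` cells, flagged in the `insufficient` attribute.
#' @return A k x k symmetric numeric matrix with named dimensions.
#' @export
pairwise_emd <- function(samples, min_n = 5) {
  k <- length(samples)
  if (k < 2) stop("need at least 2 samples", call. = FALSE)
  nm <- names(samples)
  m <- matrix(0, k, k, dimnames = list(nm, nm))
  small <- vapply(samples, length, integer(1)) < min_n
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- if (small[i] || small[j]) {
        NA_real_
      } else {
        emd_1d(samples[[i]], samples[[j]])
      }
    }
  }
  attr(m, "insufficient") <- nm[small]
  m
}

#' Pairwise rank-test significance matrix with threshold marks
#'
#' Two-group Kruskal-Wallis (equivalent to the Wilcoxon rank-sum up to the
#' chi-square approximation) for every pair of emotions, with significance
#' marks at p < 0.01 ("**") and p < 0.05 ("*"). Raw p-values are reported by
#' default; set `adjust = "BH"` for Benjamini-Hochberg correction across the
#' pairs.
#'
#' @inheritParams pairwise_emd
#' @param adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return A list: `p` (symmetric matrix, diagonal 1), `marks` (character
#'   matrix: `"**"`, `"*"` or `""`).
#' @export
pairwise_significance <- function(samples, adjust = "none") {
  k <- length(samples)
  if (k < 2) stop("need at least 2 samples", call. = FALSE)
  nm <- names(samples)
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  pairs <- utils::combn(k, 2)
  pv <- apply(pairs, 2, function(ij) {
    a <- samples[[ij[1]]]
    b <- samples[[ij[2]]]
    if (length(unique(c(a, b))) == 1) {
      return(1)
    }
    stats::kruskal.test(
      c(a, b), factor(rep(c("a", "b"), c(length(a), length(b))))
    )$p.value
  })
  if (adjust != "none") pv <- stats::p.adjust(pv, method = adjust)
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1, c_i]
    j <- pairs[2, c_i]
    p[i, j] <- p[j, i] <- pv[c_i]
  }
  marks <- matrix("", k, k, dimnames = list(nm, nm))
  marks[p < 0.05] <- "*"
  marks[p < 0.01] <- "**"
  diag(marks) <- ""
  list(p = p, marks = marks)
}
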
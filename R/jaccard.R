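# Jaccard-Tanimoto similarity between variable lists and its resampling
# p-value.
#
# The null model redraws both lists independently as uniformly random
# subsets of the universe with the observed sizes; the p-value is the
# probability of observing a Jaccard coefficient no larger than the one
# observed (dissimilarity at least as extreme as seen).  Under this null
# the coefficient depends only on the intersection size k, which follows a
# hypergeometric law, so the exact p-value is a finite sum over k; the
# Monte-Carlo route redraws actual subsets and serves as an independent
# check.

#' Jaccard-Tanimoto coefficient of two variable lists
#'
#' @param list_x,list_y Character vectors (treated as sets).
#' @return \code{|intersection| / |union|} in \[0, 1\]; \code{NA} with a
#'   warning when both sets are empty (the coefficient is undefined there,
#'   neither 0 nor 1).
#' @examples
#' jaccard(c("v1", "v2", "v3"), c("v1", "v2"))  # 2/3
#' @export
jaccard <- function(list_x, list_y) {
  x <- unique(list_x); y <- unique(list_y)
  if (length(x) == 0L && length(y) == 0L) {
    warning("Jaccard coefficient undefined for two empty sets", call. = FALSE)
    return(NA_real_)
  }
  length(intersect(x, y)) / length(union(x, y))
}

#' Resampling p-value for a Jaccard-Tanimoto comparison
#'
#' Computes \eqn{p = P(J(x', y') \le J_{obs})} where \eqn{x'} and \eqn{y'}
#' are independent uniformly random subsets of \code{universe} with the
#' observed sizes \eqn{|x|} and \eqn{|y|}.  Method \code{"exact"} sums the
#' hypergeometric distribution of the intersection size, which enumerates
#' the null exactly for any universe size; \code{"montecarlo"} redraws
#' subsets explicitly with the given seed.
#'
#' @param list_x,list_y Character vectors (sets); must be subsets of
#'   \code{universe}.
#' @param universe Character vector; defaults to \code{union(list_x, list_y)}.
#' @param method \code{"exact"} (default) or \code{"montecarlo"}.
#' @param draws Number of Monte-Carlo draws (ignored for exact).
#' @param seed Integer seed, required for \code{"montecarlo"}.
#' @return The p-value in \[0, 1\].
#' @examples
#' # identical-universe subset comparison: p = 1
#' jaccard_pvalue(c("v1", "v2", "v3"), c("v1", "v2"))
#' @export
jaccard_pvalue <- function(list_x, list_y,
                           universe = union(list_x, list_y),
                           method = c("exact", "montecarlo"),
                           draws = 10000L, seed = NULL) {
  method <- match.arg(method)
  x <- unique(list_x); y <- unique(list_y); u <- unique(universe)
  if (!all(x %in% u) || !all(y %in% u)) {
    stop("list_x and list_y must be subsets of the universe")
  }
  m <- length(x); n <- length(y); N <- length(u)
  if (m > N || n > N) stop("set sizes exceed the universe size")
  if (m == 0L && n == 0L) {
    stop("both sets empty: Jaccard comparison undefined")
  }
  j_obs <- jaccard(x, y)
  eps <- 1e-12

  if (method == "exact") {
    k <- seq(max(0L, m + n - N), min(m, n))
    jk <- ifelse(m + n - k == 0L, NA_real_, k / (m + n - k))
    w <- stats::dhyper(k, m, N - m, n)
    return(min(1, max(0, sum(w[!is.na(jk) & jk <= j_obs + eps]))))
  }

  if (draws < 1L) stop("draws must be >= 1 for montecarlo")
  if (is.null(seed)) stop("a seed is required for montecarlo")
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(draws)) {
    xi <- sample.int(N, m)
    yi <- sample.int(N, n)
    k <- sum(xi %in% yi)
    jprime <- k / (m + n - k)
    if (jprime <= j_obs + eps) hits <- hits + 1L
  }
  hits / draws
}
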
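# Shared statistical kernel. Every routine is a thin, contract-enforcing
# wrapper around the corresponding base R distribution function or test; the
# pipeline never re-derives a standard distribution.

#' Upper tail of the binomial distribution
#'
#' `P(X >= m)` for `X ~ Binomial(n, p0)`. This is the one-sided site- and
#' gene-level methylation test: "methylated" only asks for an excess of
#' methylated reads (or sites) over the null rate.
#'
#' @param m observed successes (vectorised).
#' @param n number of trials.
#' @param p0 null success probability.
#' @return probability vector.
#' @examples
#' binomUpperTail(5, 5, 0.005)
#' @export
binomUpperTail <- function(m, n, p0) {
  if (any(m < 0) || any(m > n)) stop("require 0 <= m <= n")
  if (any(p0 < 0) || any(p0 > 1)) stop("p0 must be a probability")
  stats::pbinom(m - 1, n, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up q-values, capped at 1, input order preserved.
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of q-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-squared with 1 df.
#' A table with a zero margin carries no information: statistic 0, p 1, with
#' a warning.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `statistic` and `p_value`.
#' @examples
#' chi2TwoByTwo(matrix(c(20, 10, 10, 20), 2))
#' @export
chi2TwoByTwo <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in 2x2 table; returning statistic 0, p = 1")
    return(list(statistic = 0, p_value = 1))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table. Zero-margin tables return p = 1.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `p_value` and the conditional odds ratio estimate.
#' @examples
#' fisherTwoByTwo(matrix(c(3, 0, 0, 3), 2))
#' @export
fisherTwoByTwo <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p_value = 1, odds_ratio = NA_real_))
  ht <- stats::fisher.test(tab)
  list(p_value = unname(ht$p.value), odds_ratio = unname(ht$estimate))
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= x)` when drawing `n` items without replacement from a population
#' of `N` containing `K` successes.
#'
#' @param x observed successes among the draws.
#' @param N population size.
#' @param K successes in the population.
#' @param n number of draws.
#' @return probability.
#' @examples
#' hypergeomUpperTail(5, 10, 5, 5)
#' @export
hypergeomUpperTail <- function(x, N, K, n) {
  if (K > N || n > N || x < 0 || x > min(n, K)) stop("infeasible hypergeometric arguments")
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups. The exact null distribution
#' is used for small pooled samples (n1 + n2 <= 12) without ties; otherwise
#' the tie-corrected normal approximation. Two identical constant groups are
#' maximally non-significant by convention (U = n1*n2/2, p = 1).
#'
#' @param group1,group2 numeric vectors, both non-empty.
#' @return list with `statistic` (U for group1) and `p_value`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
#' @export
mannWhitneyU <- function(group1, group2) {
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  pooled <- c(group1, group2)
  r <- rank(pooled)
  n1 <- length(group1); n2 <- length(group2)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(list(statistic = n1 * n2 / 2, p_value = 1))
  exact <- (n1 + n2 <= 12L) && !anyDuplicated(pooled)
  ht <- suppressWarnings(
    stats::wilcox.test(group1, group2, exact = exact, correct = FALSE))
  list(statistic = unname(u1), p_value = unname(ht$p.value))
}

#' Term (pathway) enrichment by Fisher's exact test
#'
#' For each annotation term, tests the 2x2 membership table (in the gene set
#' vs not) x (annotated with the term vs not) over the supplied universe, and
#' adjusts across terms with Benjamini-Hochberg. Terms with no annotated gene
#' in the universe are skipped.
#'
#' @param geneSet character vector of gene ids, a subset of `universe`.
#' @param universe character vector of all eligible gene ids.
#' @param annotation named list, term -> character vector of gene ids.
#' @return data.frame with term, counts, p_value and q_value, one row per
#'   tested term, ordered as in `annotation`.
#' @export
termEnrichment <- function(geneSet, universe, annotation) {
  geneSet <- unique(geneSet); universe <- unique(universe)
  if (!all(geneSet %in% universe)) stop("geneSet must be a subset of universe")
  rows <- lapply(names(annotation), function(term) {
    ann <- intersect(annotation[[term]], universe)
    if (!length(ann)) return(NULL)
    a <- length(intersect(geneSet, ann))
    b <- length(geneSet) - a
    cc <- length(ann) - a
    d <- length(universe) - length(geneSet) - cc
    ft <- fisherTwoByTwo(matrix(c(a, b, cc, d), 2L, byrow = TRUE))
    data.frame(term = term, set_annotated = a, set_size = length(geneSet),
               universe_annotated = length(ann),
               universe_size = length(universe),
               p_value = ft$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), set_annotated = integer(0),
                      set_size = integer(0), universe_annotated = integer(0),
                      universe_size = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  out$q_value <- bhAdjust(out$p_value)
  rownames(out) <- NULL
  out
}
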
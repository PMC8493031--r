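# Expression-robustness statistics: RPKM, the |e1 - e2| normalized
# expression-difference statistic, and group comparisons of expression
# difference across methylation/convergence categories.

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = 1e9 * count / (gene length * library size)`. Genes with no reads
#' in any library are discarded.
#'
#' @param counts integer matrix, genes x samples, with row names.
#' @param geneLengths named numeric vector of gene lengths in bp.
#' @param librarySizes mapped-read totals per sample; defaults to the
#'   column sums of `counts`.
#' @return numeric matrix of RPKM values for the retained genes.
#' @export
computeRPKM <- function(counts, geneLengths,
                        librarySizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)),
            all(rownames(counts) %in% names(geneLengths)))
  len <- geneLengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive")
  if (any(librarySizes <= 0)) stop("library sizes must be positive")
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  1e9 * sweep(counts / len[keep], 2L, librarySizes, "/")
}

#' Absolute normalized expression difference |e1 - e2|
#'
#' Per gene: replicate RPKM values are averaged within each condition, the
#' means are log10-transformed, genes with log10 RPKM <= 0.01 in either
#' condition are dropped, each condition's vector is z-normalized across
#' genes (mean 0, sample variance 1), and the statistic is the absolute
#' difference of the two normalized values. The z-normalization makes the
#' statistic invariant to positive affine transforms of either condition's
#' log-mean vector.
#'
#' @param rpkm numeric matrix, genes x samples.
#' @param conditions character/factor of length `ncol(rpkm)` with values
#'   "treated" and "control".
#' @return data.frame: gene_id, mean_log10_treated, mean_log10_control,
#'   e1 (treated, z-scored), e2 (control), abs_diff.
#' @export
expressionDifference <- function(rpkm, conditions) {
  conditions <- as.character(conditions)
  stopifnot(length(conditions) == ncol(rpkm),
            all(conditions %in% c("treated", "control")))
  m1 <- rowMeans(rpkm[, conditions == "treated", drop = FALSE])
  m2 <- rowMeans(rpkm[, conditions == "control", drop = FALSE])
  l1 <- log10(m1); l2 <- log10(m2)
  keep <- l1 > 0.01 & l2 > 0.01
  if (sum(keep) < 2L)
    stop("fewer than two genes survive the expression filter")
  e1 <- as.numeric(scale(l1[keep]))
  e2 <- as.numeric(scale(l2[keep]))
  data.frame(gene_id = rownames(rpkm)[keep],
             mean_log10_treated = l1[keep], mean_log10_control = l2[keep],
             e1 = e1, e2 = e2, abs_diff = abs(e1 - e2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare expression difference between gene categories
#'
#' Pairwise two-sided Mann-Whitney U tests on `abs_diff` (or any supplied
#' statistic) between gene categories, with per-category medians and
#' interquartile ranges. Singleton categories are flagged.
#'
#' @param profiles data.frame from [expressionDifference()].
#' @param geneGroups named character vector, gene id -> category.
#' @param value column of `profiles` to compare (default "abs_diff").
#' @return list with `summary` (per category: n, median, q1, q3) and
#'   `tests` (per category pair: U statistic and p-value).
#' @export
compareExpressionGroups <- function(profiles, geneGroups,
                                    value = "abs_diff") {
  grp <- geneGroups[profiles$gene_id]
  keep <- !is.na(grp)
  v <- profiles[[value]][keep]
  grp <- grp[keep]
  cats <- sort(unique(grp))
  if (length(cats) < 2L) stop("need at least two categories with genes")
  sizes <- table(grp)
  if (any(sizes == 1L))
    warning("singleton categor(ies): ",
            paste(names(sizes)[sizes == 1L], collapse = ", "))
  summ <- do.call(rbind, lapply(cats, function(cc) {
    x <- v[grp == cc]
    data.frame(category = cc, n = length(x), median = stats::median(x),
               q1 = unname(stats::quantile(x, 0.25)),
               q3 = unname(stats::quantile(x, 0.75)),
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(cats, 2L, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    mw <- mannWhitneyU(v[grp == pr[1L]], v[grp == pr[2L]])
    data.frame(group1 = pr[1L], group2 = pr[2L], U = mw$statistic,
               p_value = mw$p_value, stringsAsFactors = FALSE)
  }))
  list(summary = summ, tests = tests)
}

#' Filter an external differential-expression table
#'
#' Applies the standard thresholds (BH FDR < `alphaFdr` and at least
#' `minFold`-fold change) to a differential-expression result table produced
#' elsewhere; the package consumes, never fits, such tables.
#'
#' @param deTable data.frame with columns gene_id, log2_fold_change, padj.
#' @param alphaFdr FDR threshold (default 0.05).
#' @param minFold minimum fold change (default 2).
#' @return the rows of `deTable` passing both thresholds.
#' @export
filterDEGs <- function(deTable, alphaFdr = 0.05, minFold = 2) {
  stopifnot(all(c("gene_id", "log2_fold_change", "padj") %in% names(deTable)))
  keep <- !is.na(deTable$padj) & deTable$padj < alphaFdr &
    abs(deTable$log2_fold_change) >= log2(minFold)
  deTable[keep, , drop = FALSE]
}

#' Correlation between per-gene methylation and expression changes
#'
#' Pearson correlation test on matched per-gene deltas, the one-line check
#' of whether methylation changes track expression changes.
#'
#' @param methylationDelta,expressionDelta numeric vectors, same genes in
#'   the same order.
#' @return list with `r` and `p_value`.
#' @export
deltaCorrelation <- function(methylationDelta, expressionDelta) {
  ht <- stats::cor.test(methylationDelta, expressionDelta, method = "pearson")
  list(r = unname(ht$estimate), p_value = unname(ht$p.value))
}
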
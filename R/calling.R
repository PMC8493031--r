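# Site-level methylation calling. A cytosine is methylated when its
# methylated read count exceeds what bisulfite non-conversion alone would
# produce: one-sided binomial test with null probability 1 - conversion
# rate, BH-corrected across all cytosines of the sample.

#' Estimate the bisulfite conversion rate from an unmethylated control
#'
#' The control genome (chloroplast or spiked lambda) is unmethylated, so any
#' methylated read there is a conversion failure. The rate is estimated from
#' pooled counts: `1 - sum(methylated reads) / sum(all reads)`, independent
#' of how the reads are distributed across control cytosines.
#'
#' @param controlSites cytosine table from the control genome.
#' @return conversion rate in [0, 1].
#' @export
estimateConversionRate <- function(controlSites) {
  validateCytosineTable(controlSites)
  total <- sum(controlSites$count_meth) + sum(controlSites$count_unmeth)
  if (total == 0) stop("control sites carry zero total coverage")
  1 - sum(controlSites$count_meth) / total
}

#' Call methylated cytosines in one sample
#'
#' Per site with coverage >= 1, the one-sided binomial p-value of the
#' methylated read count against null probability `1 - conversionRate`,
#' BH-adjusted across all tested cytosines of the sample jointly (contexts
#' are separated only afterwards, when levels are computed). A site is
#' methylated iff its q-value falls below `alphaFdr`.
#'
#' @param sample a [MethylomeSample-class].
#' @param alphaFdr FDR threshold (default 0.05).
#' @return data.frame: chrom, pos, strand, context, count_meth, count_unmeth,
#'   coverage, p_value, q_value, status ("methylated"/"unmethylated").
#' @export
callSites <- function(sample, alphaFdr = 0.05) {
  stopifnot(is(sample, "MethylomeSample"))
  x <- siteTable(sample)
  coverage <- x$count_meth + x$count_unmeth
  keep <- coverage >= 1L
  x <- x[keep, , drop = FALSE]
  coverage <- coverage[keep]
  p0 <- 1 - conversionRate(sample)
  if (p0 == 0) {
    # degenerate null of a perfect conversion control: any methylated read
    # is impossible under the null
    p <- ifelse(x$count_meth > 0, 0, 1)
  } else {
    p <- binomUpperTail(x$count_meth, coverage, p0)
  }
  q <- bhAdjust(p)
  data.frame(chrom = x$chrom, pos = x$pos, strand = x$strand,
             context = x$context, count_meth = x$count_meth,
             count_unmeth = x$count_unmeth, coverage = coverage,
             p_value = p, q_value = q,
             status = c("unmethylated", "methylated")[1L + (q < alphaFdr)],
             stringsAsFactors = FALSE)
}

#' Replicate-consensus methylation status
#'
#' Applies the coverage filter first, then the consistency vote: within each
#' replicate only cytosines covered by at least `minSiteReads` reads are
#' eligible, and a site is retained iff at least two eligible replicates
#' agree on its status (the majority status when replicates disagree; a
#' site is dropped when no status reaches two votes or fewer than two
#' replicates are eligible). Pooled read counts over the eligible replicates
#' are carried forward for gene-level aggregation. The result is invariant
#' to replicate order.
#'
#' @param calls list of >= 2 per-replicate call tables from [callSites()].
#' @param minSiteReads minimum per-replicate coverage (default 3).
#' @return data.frame: chrom, pos, strand, context, status, n_eligible,
#'   votes, pooled_meth, pooled_total.
#' @export
consensusReplicates <- function(calls, minSiteReads = 3L) {
  if (length(calls) < 2L) stop("at least two replicates are required")
  chrom_levels <- unique(unlist(lapply(calls, function(x) unique(x$chrom)),
                                use.names = FALSE))
  # numeric site key: exact in double precision for positions < 2^31
  site_key <- function(x, rows) {
    (match(x$chrom[rows], chrom_levels) * 2 +
       (x$strand[rows] == "+")) * 2^31 + x$pos[rows]
  }
  elig_rows <- lapply(calls, function(x) which(x$coverage >= minSiteReads))
  keys <- lapply(seq_along(calls),
                 function(r) site_key(calls[[r]], elig_rows[[r]]))
  all_keys <- unique(unlist(keys, use.names = FALSE))
  n <- length(all_keys)
  meth_votes <- integer(n); unmeth_votes <- integer(n)
  pooled_meth <- integer(n); pooled_total <- integer(n)
  context <- character(n); chrom <- character(n)
  pos <- integer(n); strand <- character(n)
  seen <- logical(n)
  for (r in seq_along(calls)) {
    rows <- elig_rows[[r]]
    x <- calls[[r]]
    idx <- match(keys[[r]], all_keys)
    is_meth <- x$status[rows] == "methylated"
    meth_votes[idx] <- meth_votes[idx] + as.integer(is_meth)
    unmeth_votes[idx] <- unmeth_votes[idx] + as.integer(!is_meth)
    pooled_meth[idx] <- pooled_meth[idx] + x$count_meth[rows]
    pooled_total[idx] <- pooled_total[idx] + x$coverage[rows]
    new <- !seen[idx]
    ni <- idx[new]
    seen[ni] <- TRUE
    context[ni] <- x$context[rows][new]
    chrom[ni] <- x$chrom[rows][new]
    pos[ni] <- x$pos[rows][new]
    strand[ni] <- x$strand[rows][new]
  }
  votes <- pmax(meth_votes, unmeth_votes)
  eligible <- meth_votes + unmeth_votes
  keep <- eligible >= 2L & votes >= 2L & meth_votes != unmeth_votes
  out <- data.frame(
    chrom = chrom[keep],
    pos = pos[keep],
    strand = strand[keep],
    context = context[keep],
    status = ifelse(meth_votes[keep] > unmeth_votes[keep],
                    "methylated", "unmethylated"),
    n_eligible = eligible[keep],
    votes = votes[keep],
    pooled_meth = pooled_meth[keep],
    pooled_total = pooled_total[keep],
    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

#' Genome-wide (or regional) methylation level
#'
#' Proportion of methylated cytosines among retained cytosines of a context,
#' optionally restricted to a region set (e.g. CDS or TE intervals).
#'
#' @param consensus consensus table from [consensusReplicates()].
#' @param context one of "CG", "CHG", "CHH".
#' @param region optional `GRanges`; only sites falling inside are counted.
#' @return proportion in [0, 1], or `NA` when no site is retained.
#' @export
methylationLevel <- function(consensus, context, region = NULL) {
  x <- consensus[consensus$context == context, , drop = FALSE]
  if (!is.null(region)) {
    gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
    hit <- IRanges::overlapsAny(gr, region, ignore.strand = TRUE)
    x <- x[hit, , drop = FALSE]
  }
  if (!nrow(x)) return(NA_real_)
  mean(x$status == "methylated")
}
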
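# Salt-treatment comparison: per-cytosine binomial GLM for differentially
# methylated positions (DMPs), condition-wise gene classification for
# differentially methylated genes (DMGs), genic enrichment of DMPs, and the
# stratified contingency analysis relating salt-induced gbM changes to
# evolutionary convergence.

#' Call differentially methylated positions (DMPs)
#'
#' Per cytosine covered by at least `minDmpReads` reads in every one of the
#' six libraries (three treated, three control), a binomial-logit GLM of the
#' methylated/unmethylated read counts on treatment plus replicate index
#' (the replicate index 1..3 is shared across conditions so that the
#' treatment effect stays estimable). The Wald p-value of the treatment
#' coefficient is BH-adjusted across all tested sites; a site is a DMP iff
#' q < `alphaFdr`, with direction given by the sign of the coefficient.
#' Sites whose fit flags quasi-separation fall back to a likelihood-ratio
#' test of the treatment term; sites that are all-unmethylated or
#' all-methylated across the six libraries carry no treatment information
#' and are reported with p = 1 and `degenerate = TRUE`.
#'
#' @param control,treated lists of three cytosine tables each (replicates
#'   1..3, in pairing order).
#' @param minDmpReads minimum coverage in every library (default 5).
#' @param alphaFdr FDR threshold (default 0.05).
#' @return data.frame: chrom, pos, strand, context, estimate (treatment
#'   log-odds), p_value, q_value, direction ("gain"/"loss"), degenerate,
#'   is_dmp.
#' @export
callDMPs <- function(control, treated, minDmpReads = 5L, alphaFdr = 0.05) {
  stopifnot(length(control) == 3L, length(treated) == 3L)
  reps <- c(control, treated)
  keys <- lapply(reps, function(x) paste(x$chrom, x$pos, x$strand, sep = "\r"))
  common <- Reduce(intersect, keys)
  idx <- lapply(seq_along(reps), function(r) match(common, keys[[r]]))
  meth <- vapply(seq_along(reps),
                 function(r) reps[[r]]$count_meth[idx[[r]]],
                 integer(length(common)))
  unmeth <- vapply(seq_along(reps),
                   function(r) reps[[r]]$count_unmeth[idx[[r]]],
                   integer(length(common)))
  if (length(common) == 1L) { meth <- rbind(meth); unmeth <- rbind(unmeth) }
  cov_ok <- rowSums((meth + unmeth) >= minDmpReads) == 6L
  meth <- meth[cov_ok, , drop = FALSE]
  unmeth <- unmeth[cov_ok, , drop = FALSE]
  common <- common[cov_ok]
  first <- reps[[1L]][idx[[1L]][cov_ok], , drop = FALSE]

  treatment <- factor(rep(c("control", "treated"), each = 3L),
                      levels = c("control", "treated"))
  individual <- factor(rep(1:3, times = 2L))
  X <- stats::model.matrix(~ treatment + individual)
  X0 <- X[, colnames(X) != "treatmenttreated", drop = FALSE]
  t_col <- which(colnames(X) == "treatmenttreated")

  n <- length(common)
  est <- numeric(n); p <- numeric(n); degenerate <- logical(n)
  for (i in seq_len(n)) {
    mi <- meth[i, ]; ui <- unmeth[i, ]
    if (sum(mi) == 0L || sum(ui) == 0L) {
      est[i] <- 0; p[i] <- 1; degenerate[i] <- TRUE
      next
    }
    tot <- mi + ui
    fit <- suppressWarnings(
      stats::glm.fit(X, mi / tot, weights = tot, family = stats::binomial()))
    cf <- fit$coefficients[t_col]
    rk <- fit$rank
    cov_unscaled <- chol2inv(fit$qr$qr[seq_len(rk), seq_len(rk), drop = FALSE])
    se <- sqrt(diag(cov_unscaled))[t_col]
    separated <- !fit$converged || abs(cf) > 15 || se > 1e3
    if (separated) {
      fit0 <- suppressWarnings(
        stats::glm.fit(X0, mi / tot, weights = tot, family = stats::binomial()))
      p[i] <- stats::pchisq(fit0$deviance - fit$deviance, df = 1,
                            lower.tail = FALSE)
    } else {
      p[i] <- 2 * stats::pnorm(-abs(cf / se))
    }
    est[i] <- cf
  }
  q <- bhAdjust(p)
  data.frame(chrom = first$chrom, pos = first$pos, strand = first$strand,
             context = first$context, estimate = est, p_value = p,
             q_value = q, direction = ifelse(est > 0, "gain", "loss"),
             degenerate = degenerate, is_dmp = q < alphaFdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genic enrichment of DMPs
#'
#' Hypergeometric upper-tail test of whether DMPs fall in genic regions more
#' often than expected from the genic fraction of all tested sites.
#'
#' @param dmpTable output of [callDMPs()].
#' @param genes `GRangesList` of gene CDS intervals.
#' @return list: x (genic DMPs), n (DMPs), K (genic tested sites),
#'   N (tested sites), p_value.
#' @export
genicEnrichment <- function(dmpTable, genes) {
  if (!nrow(dmpTable) || !sum(dmpTable$is_dmp))
    return(list(x = 0L, n = 0L, K = 0L, N = nrow(dmpTable), p_value = 1))
  gr <- GenomicRanges::GRanges(dmpTable$chrom,
                               IRanges::IRanges(dmpTable$pos, dmpTable$pos))
  genic <- IRanges::overlapsAny(gr, genes, ignore.strand = TRUE)
  N <- nrow(dmpTable)
  K <- sum(genic)
  n <- sum(dmpTable$is_dmp)
  x <- sum(genic & dmpTable$is_dmp)
  list(x = x, n = n, K = K, N = N, p_value = hypergeomUpperTail(x, N, K, n))
}

#' Call differentially methylated genes (DMGs)
#'
#' Runs the full site-calling, consensus and gene-classification chain for
#' the treated and control replicate sets separately (each condition with
#' its own genome background), then compares classes: UM -> BM is a gained
#' gbM gene, BM -> UM a lost one; genes mCHG, mCHH or unclassifiable in
#' either condition are excluded.
#'
#' @param controlSamples,treatedSamples lists of [MethylomeSample-class]
#'   replicates.
#' @param genes `GRangesList` of CDS intervals per gene.
#' @param config a [PipelineConfig-class].
#' @return data.frame: gene_id, class_control, class_treated, status in
#'   gained_gbM/lost_gbM/unchanged/excluded.
#' @export
callDMGs <- function(controlSamples, treatedSamples, genes,
                     config = pipelineConfig()) {
  ctrl <- classifyGeneSet(controlSamples, genes, config)$classes
  trt <- classifyGeneSet(treatedSamples, genes, config)$classes
  stopifnot(identical(ctrl$gene_id, trt$gene_id))
  cc <- ctrl$class; ct <- trt$class
  status <- rep("excluded", length(cc))
  both_ok <- cc %in% c("BM", "UM") & ct %in% c("BM", "UM")
  status[both_ok & cc == ct] <- "unchanged"
  status[both_ok & cc == "UM" & ct == "BM"] <- "gained_gbM"
  status[both_ok & cc == "BM" & ct == "UM"] <- "lost_gbM"
  data.frame(gene_id = ctrl$gene_id, class_control = cc, class_treated = ct,
             status = status, stringsAsFactors = FALSE)
}

#' Contingency analysis of DMGs against convergence, from counts
#'
#' The 2x2 analysis underlying the stratified report: convBMM vs other
#' genes crossed with changed vs unchanged methylation status. The
#' percentage of DMGs is `100 * changed / unchanged` (one decimal), the
#' arithmetic consistent with every stratum of the published counts, and
#' the test is the uncorrected Pearson chi-squared.
#'
#' @param convUnchanged,convChanged counts for convBMM genes.
#' @param otherUnchanged,otherChanged counts for the remaining genes.
#' @return data.frame with one row per group: group, unchanged, changed,
#'   pct_dmg, and the shared chi2_statistic / chi2_p.
#' @export
dmgContingencyCounts <- function(convUnchanged, convChanged,
                                 otherUnchanged, otherChanged) {
  tab <- matrix(c(convUnchanged, convChanged, otherUnchanged, otherChanged),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("convBMM", "others"),
                                c("unchanged", "changed")))
  ht <- chi2TwoByTwo(tab)
  data.frame(group = rownames(tab),
             unchanged = tab[, "unchanged"], changed = tab[, "changed"],
             pct_dmg = round(100 * tab[, "changed"] / tab[, "unchanged"], 1),
             chi2_statistic = ht$statistic, chi2_p = ht$p_value,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stratified DMG-vs-convergence contingency analysis
#'
#' Per baseline stratum (genes classified BM or UM in the control
#' condition), cross-tabulates convBMM membership against whether the gene
#' changed methylation status under treatment, reports the percentage of
#' DMGs in each group and the chi-squared p-value. Empty strata are
#' skipped.
#'
#' @param dmgs data.frame from [callDMGs()] (excluded genes are dropped).
#' @param convergenceLabels data.frame from [classifyConvergence()] or any
#'   data.frame with columns gene_id and label; genes absent from it count
#'   as "others".
#' @return data.frame with columns stratum, group, unchanged, changed,
#'   pct_dmg, chi2_statistic, chi2_p.
#' @export
dmgContingency <- function(dmgs, convergenceLabels) {
  x <- dmgs[dmgs$status != "excluded", , drop = FALSE]
  lab <- stats::setNames(convergenceLabels$label, convergenceLabels$gene_id)
  is_conv <- !is.na(lab[x$gene_id]) & lab[x$gene_id] == "convBMM"
  changed <- x$status %in% c("gained_gbM", "lost_gbM")
  out <- lapply(c("BM", "UM"), function(stratum) {
    s <- x$class_control == stratum
    if (!sum(s)) return(NULL)
    res <- dmgContingencyCounts(
      sum(s & is_conv & !changed), sum(s & is_conv & changed),
      sum(s & !is_conv & !changed), sum(s & !is_conv & changed))
    cbind(stratum = stratum, res, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
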
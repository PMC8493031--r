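# Gene-level classification into BM / mCHG / mCHH / UM. Per context, the
# methylated-site count within a gene's CDS is tested against the species'
# own genome-wide basal methylation level; BH across genes within each
# context; classes are assigned by a CHH > CHG > CG precedence that renders
# the four categories mutually exclusive.

#' Aggregate consensus sites over gene CDS intervals
#'
#' A cytosine contributes to a gene iff its position lies within a CDS
#' interval of that gene's primary transcript (closed intervals, boundary
#' positions included; either DNA strand counts). Genes spanning no retained
#' site get (0, 0) and will later be unclassifiable.
#'
#' @param consensus consensus table from [consensusReplicates()].
#' @param genes `GRangesList` of merged CDS intervals per gene
#'   (see [readGeneAnnotation()]).
#' @return data.frame with one row per gene x context: gene_id, context,
#'   m (methylated sites), n (all retained sites).
#' @export
aggregateGeneCounts <- function(consensus, genes) {
  gene_ids <- names(genes)
  contexts <- c("CG", "CHG", "CHH")
  grid <- expand.grid(gene_id = gene_ids, context = contexts,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$gene_id, gene_ids)), , drop = FALSE]
  m <- integer(nrow(grid)); n <- integer(nrow(grid))
  if (nrow(consensus)) {
    sites <- GenomicRanges::GRanges(consensus$chrom,
                                    IRanges::IRanges(consensus$pos, consensus$pos))
    hits <- GenomicRanges::findOverlaps(sites, genes, ignore.strand = TRUE)
    if (length(hits)) {
      s_idx <- S4Vectors::queryHits(hits)
      g_idx <- S4Vectors::subjectHits(hits)
      # grid rows are gene-major with contexts CG, CHG, CHH inside each gene
      code <- (g_idx - 1L) * 3L +
        match(consensus$context[s_idx], contexts)
      n <- tabulate(code, nbins = nrow(grid))
      is_meth <- consensus$status[s_idx] == "methylated"
      m <- tabulate(code[is_meth], nbins = nrow(grid))
    }
  }
  data.frame(gene_id = grid$gene_id, context = grid$context, m = m, n = n,
             stringsAsFactors = FALSE)
}

#' Genome-wide basal methylation per context
#'
#' The species' own background for the gene-level binomial test: the
#' genome-wide proportion of methylated cytosines of each context among
#' retained consensus sites.
#'
#' @param consensus consensus table from [consensusReplicates()].
#' @return named numeric vector with entries CG, CHG, CHH.
#' @export
computeBackground <- function(consensus) {
  out <- vapply(c("CG", "CHG", "CHH"),
                function(cc) methylationLevel(consensus, cc), numeric(1))
  if (any(is.na(out)))
    stop("no retained sites for context(s): ",
         paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Classify genes as BM, mCHG, mCHH or UM
#'
#' Per context, p = P(X >= m | Binomial(n, basal)) and BH adjustment across
#' genes within the context. Classes follow a CHH > CHG > CG precedence:
#' mCHH iff q_CHH < alpha; otherwise mCHG iff q_CHG < alpha; otherwise BM
#' (body-methylated) iff q_CG < alpha; otherwise UM. A context's q-value is
#' only trusted when the gene carries at least `minGeneSites` cytosines of
#' that context; a gene whose decision would consult an under-covered
#' context is unclassifiable.
#'
#' @param geneCounts per-gene per-context (m, n) from [aggregateGeneCounts()].
#' @param background named basal levels from [computeBackground()].
#' @param alphaFdr FDR threshold (default 0.05).
#' @param minGeneSites minimum cytosines per consulted context (default 20).
#' @return data.frame, one row per gene: gene_id, m/n and q per context,
#'   and `class` in BM/mCHG/mCHH/UM/unclassifiable.
#' @export
classifyGenes <- function(geneCounts, background, alphaFdr = 0.05,
                          minGeneSites = 20L) {
  stopifnot(all(c("CG", "CHG", "CHH") %in% names(background)))
  wide <- list()
  for (cc in c("CG", "CHG", "CHH")) {
    sub <- geneCounts[geneCounts$context == cc, , drop = FALSE]
    p <- binomUpperTail(sub$m, sub$n, background[[cc]])
    q <- bhAdjust(p)
    wide[[cc]] <- data.frame(gene_id = sub$gene_id, m = sub$m, n = sub$n,
                             q = q, stringsAsFactors = FALSE)
  }
  ids <- wide$CG$gene_id
  stopifnot(identical(ids, wide$CHG$gene_id), identical(ids, wide$CHH$gene_id))
  ok <- function(cc) wide[[cc]]$n >= minGeneSites
  sig <- function(cc) wide[[cc]]$q < alphaFdr

  cls <- rep("unclassifiable", length(ids))
  # decision walks CHH, then CHG, then CG; each step requires sufficient
  # cytosine content in the context it consults
  undecided <- ok("CHH")
  cls[undecided & sig("CHH")] <- "mCHH"
  undecided <- undecided & !sig("CHH") & ok("CHG")
  cls[undecided & sig("CHG")] <- "mCHG"
  undecided <- undecided & !sig("CHG") & ok("CG")
  cls[undecided & sig("CG")] <- "BM"
  cls[undecided & !sig("CG")] <- "UM"

  data.frame(gene_id = ids,
             m_CG = wide$CG$m, n_CG = wide$CG$n, q_CG = wide$CG$q,
             m_CHG = wide$CHG$m, n_CHG = wide$CHG$n, q_CHG = wide$CHG$q,
             m_CHH = wide$CHH$m, n_CHH = wide$CHH$n, q_CHH = wide$CHH$q,
             class = cls, stringsAsFactors = FALSE)
}

#' Full per-sample-set gene classification chain
#'
#' Convenience wrapper: per-replicate site calls, replicate consensus,
#' genome background, CDS aggregation and gene classification in one step.
#'
#' @param samples list of [MethylomeSample-class] replicates (>= 2).
#' @param genes `GRangesList` of CDS intervals per gene.
#' @param config a [PipelineConfig-class].
#' @return list with elements `consensus`, `background` and `classes`
#'   (the [classifyGenes()] table).
#' @export
classifyGeneSet <- function(samples, genes, config = pipelineConfig()) {
  calls <- lapply(samples, callSites, alphaFdr = config@alphaFdr)
  consensus <- consensusReplicates(calls, minSiteReads = config@minSiteReads)
  background <- computeBackground(consensus)
  counts <- aggregateGeneCounts(consensus, genes)
  classes <- classifyGenes(counts, background, alphaFdr = config@alphaFdr,
                           minGeneSites = config@minGeneSites)
  list(consensus = consensus, background = background, classes = classes)
}
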
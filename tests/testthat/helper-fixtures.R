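# Small in-code fixtures shared by the tests.

TRI_OF <- c(CG = "CGA", CHG = "CAG", CHH = "CAT")

makeSites <- function(pos, meth, unmeth, context = "CG", chrom = "chr1",
                      strand = "+") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             count_meth = as.integer(meth), count_unmeth = as.integer(unmeth),
             context = context, trinucleotide = unname(TRI_OF[context]),
             stringsAsFactors = FALSE)
}

makeSample <- function(sites, conversionRate = 0.995, id = "s1",
                       species = "TestSp") {
  methylomeSample(id, species, conversionRate, sites)
}

randomCytosineTable <- function(n) {
  ctx <- sample(c("CG", "CHG", "CHH"), n, replace = TRUE)
  makeSites(pos = sort(sample.int(10 * n, n)),
            meth = rpois(n, 3), unmeth = rpois(n, 5),
            context = ctx,
            chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
            strand = sample(c("+", "-"), n, replace = TRUE))
}

# a one-interval gene model list
makeGenes <- function(starts, ends, ids = sprintf("g%d", seq_along(starts)),
                      chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                               strand = "+", gene_id = ids)
  grl <- GenomicRanges::split(gr, gr$gene_id)[ids]
  S4Vectors::mcols(grl)$gene_id <- ids
  S4Vectors::mcols(grl)$transcript_id <- paste0(ids, ".1")
  grl
}

leafVec <- function(bits) {
  # bits: logical named over the seven species, TRUE = BM
  ifelse(bits, "BM", "UM")
}
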
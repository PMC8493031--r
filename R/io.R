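# Readers and writers for the plain-text formats the pipeline consumes:
# Bismark-style cytosine reports, GFF3/BED12 gene models, ortholog cluster
# tables and Newick trees. All coordinates are held internally as 1-based
# closed intervals, the convention of the cytosine report itself; BED input
# is converted on read.

#' Read a Bismark-style cytosine report
#'
#' Seven tab-separated columns without a header: chromosome, 1-based
#' position, strand, methylated read count, unmethylated read count, context
#' (CG/CHG/CHH) and trinucleotide. Every row is validated; malformed input
#' fails loudly rather than being coerced.
#'
#' @param path file path.
#' @return data.frame with columns chrom, pos, strand, count_meth,
#'   count_unmeth, context, trinucleotide; row order as in the file.
#' @seealso [writeCytosineReport()]
#' @export
readCytosineReport <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (is.null(fields) || !length(fields))
    return(emptyCytosineTable())
  bad <- which(fields != 7L)
  if (length(bad))
    stop("malformed cytosine report: expected 7 tab-separated columns, line ",
         bad[1L], " has ", fields[bad[1L]])
  x <- utils::read.table(path, sep = "\t", quote = "", header = FALSE,
                         col.names = CYTOSINE_COLUMNS,
                         colClasses = c("character", "integer", "character",
                                        "integer", "integer", "character",
                                        "character"))
  validateCytosineTable(x)
  x
}

emptyCytosineTable <- function() {
  data.frame(chrom = character(0), pos = integer(0), strand = character(0),
             count_meth = integer(0), count_unmeth = integer(0),
             context = character(0), trinucleotide = character(0),
             stringsAsFactors = FALSE)
}

#' Write a cytosine report
#'
#' @param x validated cytosine table (see [readCytosineReport()]).
#' @param path output file path.
#' @return invisibly `path`.
#' @export
writeCytosineReport <- function(x, path) {
  validateCytosineTable(x)
  utils::write.table(x[CYTOSINE_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models (primary-transcript CDS intervals)
#'
#' Parses GFF3 or BED12 via `rtracklayer` and returns, per gene, the merged
#' CDS intervals of its primary transcript as 1-based closed coordinates.
#' For GFF3, the primary transcript is the one whose attributes flag it as
#' primary/canonical when such a flag exists, otherwise the transcript with
#' the longest total CDS (ties broken by transcript id). Genes without CDS
#' features are skipped with a warning. For BED12 each record is taken as
#' one gene's primary transcript; its blocks become the CDS intervals.
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed12"`.
#' @return named `GRangesList`, one element of merged CDS ranges per gene;
#'   element metadata carries gene_id and transcript_id.
#' @export
readGeneAnnotation <- function(path, format = c("gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "gff3") readGeneAnnotationGff3(path) else readGeneAnnotationBed12(path)
}

readGeneAnnotationGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gr$type)
  tx <- gr[types %in% c("mRNA", "transcript")]
  if (!length(tx)) stop("no mRNA/transcript features in ", path)
  tx_id <- as.character(tx$ID)
  tx_gene <- vapply(tx$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                    character(1))
  cds <- gr[types == "CDS"]
  cds_tx <- vapply(cds$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                   character(1))
  cds_len <- vapply(split(GenomicRanges::width(cds), cds_tx), sum, numeric(1))
  primary_flag <- rep(FALSE, length(tx))
  for (attr_name in c("primary", "canonical", "longest")) {
    if (!is.null(S4Vectors::mcols(tx)[[attr_name]])) {
      v <- S4Vectors::mcols(tx)[[attr_name]]
      primary_flag <- primary_flag | (!is.na(v) & tolower(as.character(v)) %in%
                                        c("true", "1", "yes"))
    }
  }
  keep_tx <- character(0)
  for (g in unique(tx_gene)) {
    cand <- which(tx_gene == g)
    flagged <- cand[primary_flag[cand]]
    if (length(flagged)) cand <- flagged
    lens <- cds_len[tx_id[cand]]
    lens[is.na(lens)] <- 0
    if (all(lens == 0)) {
      warning("gene ", g, " has no CDS features; skipped")
      next
    }
    best <- cand[order(-lens, tx_id[cand])][1L]
    keep_tx <- c(keep_tx, tx_id[best])
  }
  cds_keep <- cds[cds_tx %in% keep_tx]
  grl <- GenomicRanges::reduce(
    GenomicRanges::split(cds_keep, factor(cds_tx[cds_tx %in% keep_tx],
                                          levels = keep_tx)))
  gene_of <- stats::setNames(tx_gene, tx_id)[keep_tx]
  names(grl) <- gene_of
  S4Vectors::mcols(grl)$gene_id <- gene_of
  S4Vectors::mcols(grl)$transcript_id <- keep_tx
  grl
}

readGeneAnnotationBed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks))
    stop("BED input lacks block structure; a 12-column BED is required")
  abs_blocks <- IRanges::shift(gr$blocks, GenomicRanges::start(gr) - 1L)
  grl <- GenomicRanges::GRangesList(lapply(seq_along(gr), function(i) {
    GenomicRanges::GRanges(GenomicRanges::seqnames(gr)[i], abs_blocks[[i]],
                           strand = GenomicRanges::strand(gr)[i])
  }))
  grl <- GenomicRanges::reduce(grl)
  names(grl) <- gr$name
  S4Vectors::mcols(grl)$gene_id <- gr$name
  S4Vectors::mcols(grl)$transcript_id <- gr$name
  grl
}

#' Read a 1:1 ortholog cluster table
#'
#' Tab-separated with a header line: first column the cluster id, one column
#' per species holding exactly one gene id. Rows with missing entries or a
#' wrong number of columns are a validation error, since only strict 1:1
#' clusters (one gene in every species) enter the phylogenetic analyses.
#'
#' @param path file path.
#' @param n_species expected number of species columns (default 7).
#' @return data.frame, first column `cluster_id`, then one column per species.
#' @export
readOrthologTable <- function(path, n_species = 7L) {
  if (!file.exists(path)) stop("no such file: ", path)
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  bad <- which(fields != n_species + 1L)
  if (length(bad))
    stop("ortholog table: expected ", n_species + 1L,
         " columns, line ", bad[1L], " has ", fields[bad[1L]])
  x <- utils::read.table(path, sep = "\t", quote = "", header = TRUE,
                         colClasses = "character", check.names = FALSE)
  names(x)[1L] <- "cluster_id"
  empty <- is.na(as.matrix(x)) | as.matrix(x) == ""
  if (any(empty))
    stop("ortholog table: missing gene id at row ",
         which(rowSums(empty) > 0)[1L])
  if (anyDuplicated(x$cluster_id)) stop("duplicated cluster ids")
  x
}

#' Write an ortholog cluster table
#'
#' @param x data.frame as returned by [readOrthologTable()].
#' @param path output file path.
#' @return invisibly `path`.
#' @export
writeOrthologTable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a species tree from a Newick file
#'
#' @param path Newick file path.
#' @param roles named character vector of species roles; defaults to the
#'   packaged seven-taxon design.
#' @return a [SpeciesPairTree-class] object.
#' @export
readSpeciesTree <- function(path, roles = defaultSpeciesRoles()) {
  speciesPairTree(ape::read.tree(path), roles)
}

#' Write a result table with a provenance header
#'
#' Writes a TSV preceded by `#`-prefixed comment lines recording the
#' configuration and seed, so that every result file carries its own
#' provenance.
#'
#' @param x data.frame.
#' @param path output path.
#' @param config optional `PipelineConfig` recorded in the header.
#' @return invisibly `path`.
#' @export
writeResultTable <- function(x, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(sprintf(
      "# mangroveGBM alphaFdr=%g minSiteReads=%d minDmpReads=%d minGeneSites=%d seed=%d",
      config@alphaFdr, config@minSiteReads, config@minDmpReads,
      config@minGeneSites, config@rngSeed), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
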
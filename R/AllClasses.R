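#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
NULL

CYTOSINE_COLUMNS <- c("chrom", "pos", "strand", "count_meth", "count_unmeth",
                      "context", "trinucleotide")

#' Validate a cytosine report table
#'
#' Checks a data.frame of per-cytosine counts against the Bismark-style
#' cytosine report contract: 1-based positions, +/- strand, non-negative
#' integer read counts, context in CG/CHG/CHH, and a trinucleotide consistent
#' with the declared context (H = A, C or T) whenever it contains no N.
#'
#' @param x data.frame with columns chrom, pos, strand, count_meth,
#'   count_unmeth, context, trinucleotide.
#' @return invisibly `x`; stops with an informative message on violation.
#' @keywords internal
validateCytosineTable <- function(x) {
  if (!is.data.frame(x)) stop("cytosine table must be a data.frame")
  missing_cols <- setdiff(CYTOSINE_COLUMNS, names(x))
  if (length(missing_cols))
    stop("cytosine table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$pos)) || any(x$pos < 1L) || any(x$pos != as.integer(x$pos)))
    stop("positions must be positive integers (1-based)")
  if (!all(x$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  for (cc in c("count_meth", "count_unmeth")) {
    v <- x[[cc]]
    if (any(is.na(v)) || any(v < 0L) || any(v != as.integer(v)))
      stop(cc, " must be non-negative integers")
  }
  if (!all(x$context %in% c("CG", "CHG", "CHH")))
    stop("unknown context token: ",
         paste(unique(setdiff(x$context, c("CG", "CHG", "CHH"))), collapse = ", "))
  # validate trinucleotides on their unique values, then map back
  uniq <- unique(x$trinucleotide)
  uniq_up <- toupper(uniq)
  if (!all(grepl("^[ACGTN]{3}$", uniq_up)))
    stop("trinucleotide must be 3 letters over A/C/G/T/N")
  expected_uniq <- contextFromTrinucleotide(uniq_up)
  expected_uniq[grepl("N", uniq_up, fixed = TRUE)] <- NA_character_
  expected <- expected_uniq[match(x$trinucleotide, uniq)]
  bad <- which(!is.na(expected) & expected != x$context)
  if (length(bad))
    stop("context inconsistent with trinucleotide at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  invisible(x)
}

#' Derive the methylation context from a cytosine trinucleotide
#'
#' @param tri character vector of 3-letter trinucleotides (first base C).
#' @return character vector over CG, CHG, CHH.
#' @examples
#' contextFromTrinucleotide(c("CGA", "CAG", "CTT"))
#' @export
contextFromTrinucleotide <- function(tri) {
  tri <- toupper(tri)
  out <- rep("CHH", length(tri))
  out[substr(tri, 3L, 3L) == "G"] <- "CHG"
  out[substr(tri, 2L, 2L) == "G"] <- "CG"
  out
}

#' Pipeline configuration
#'
#' Holds the thresholds shared across the pipeline: the FDR level used for
#' every Benjamini-Hochberg cut, the minimum per-replicate read depth for a
#' cytosine to enter the replicate-consensus vote, the stricter depth required
#' for differential methylation testing, the minimum number of cytosines a
#' gene needs in a consulted context to be classifiable, and the role
#' (mangrove / nonmangrove / outgroup) of each species in the pair design.
#'
#' @slot alphaFdr FDR threshold for all BH-controlled calls (default 0.05).
#' @slot minSiteReads minimum reads per replicate for site retention (default 3).
#' @slot minDmpReads minimum reads per sample for DMP testing (default 5).
#' @slot minGeneSites minimum cytosines per consulted context (default 20).
#' @slot rngSeed integer seed recorded with outputs.
#' @slot speciesRoles named character vector, species -> role.
#' @export
setClass("PipelineConfig",
         representation(alphaFdr = "numeric", minSiteReads = "integer",
                        minDmpReads = "integer", minGeneSites = "integer",
                        rngSeed = "integer", speciesRoles = "character"),
         validity = function(object) {
  msg <- character(0)
  if (object@alphaFdr <= 0 || object@alphaFdr >= 1)
    msg <- c(msg, "alphaFdr must be in (0, 1)")
  if (object@minSiteReads < 1L) msg <- c(msg, "minSiteReads must be positive")
  if (object@minDmpReads < 1L) msg <- c(msg, "minDmpReads must be positive")
  if (object@minGeneSites < 1L) msg <- c(msg, "minGeneSites must be positive")
  if (length(object@speciesRoles) &&
      !all(object@speciesRoles %in% c("mangrove", "nonmangrove", "outgroup")))
    msg <- c(msg, "speciesRoles must be mangrove/nonmangrove/outgroup")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param alphaFdr FDR threshold used for every BH-controlled decision.
#' @param minSiteReads minimum per-replicate coverage for consensus voting.
#' @param minDmpReads minimum per-sample coverage for DMP testing.
#' @param minGeneSites minimum cytosines in each consulted context.
#' @param rngSeed integer seed recorded alongside results.
#' @param speciesRoles named character vector mapping species to roles.
#' @return a `PipelineConfig` object.
#' @examples
#' pipelineConfig()
#' @export
pipelineConfig <- function(alphaFdr = 0.05, minSiteReads = 3L, minDmpReads = 5L,
                           minGeneSites = 20L, rngSeed = 1L,
                           speciesRoles = defaultSpeciesRoles()) {
  new("PipelineConfig", alphaFdr = alphaFdr,
      minSiteReads = as.integer(minSiteReads),
      minDmpReads = as.integer(minDmpReads),
      minGeneSites = as.integer(minGeneSites),
      rngSeed = as.integer(rngSeed), speciesRoles = speciesRoles)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n",
      "  alphaFdr: ", object@alphaFdr, "\n",
      "  minSiteReads: ", object@minSiteReads,
      "  minDmpReads: ", object@minDmpReads,
      "  minGeneSites: ", object@minGeneSites, "\n",
      "  species roles: ",
      paste(names(object@speciesRoles), object@speciesRoles,
            sep = "=", collapse = " "), "\n", sep = "")
})

#' A bisulfite methylome sample
#'
#' One sequencing library: per-cytosine methylated/unmethylated read counts
#' together with the bisulfite conversion rate estimated from an unmethylated
#' control genome (chloroplast or spiked lambda). `1 - conversionRate` is the
#' per-read probability of a false methylated call and serves as the null
#' probability of the site-level binomial test.
#'
#' @slot sampleId character scalar.
#' @slot species character scalar.
#' @slot conversionRate probability in (0, 1].
#' @slot sites data.frame of cytosine report rows.
#' @export
setClass("MethylomeSample",
         representation(sampleId = "character", species = "character",
                        conversionRate = "numeric", sites = "data.frame"),
         validity = function(object) {
  msg <- character(0)
  if (length(object@conversionRate) != 1L ||
      object@conversionRate <= 0 || object@conversionRate > 1)
    msg <- c(msg, "conversionRate must be a single probability in (0, 1]")
  v <- tryCatch({ validateCytosineTable(object@sites); NULL },
                error = function(e) conditionMessage(e))
  if (!is.null(v)) msg <- c(msg, v)
  if (length(msg)) msg else TRUE
})

#' Construct a MethylomeSample
#'
#' @param sampleId sample identifier.
#' @param species species name.
#' @param conversionRate bisulfite conversion rate in (0, 1].
#' @param sites cytosine report data.frame (see [readCytosineReport()]).
#' @return a `MethylomeSample`.
#' @export
methylomeSample <- function(sampleId, species, conversionRate, sites) {
  new("MethylomeSample", sampleId = sampleId, species = species,
      conversionRate = conversionRate, sites = sites)
}

setMethod("show", "MethylomeSample", function(object) {
  cat("MethylomeSample '", object@sampleId, "' (", object@species, ")\n",
      "  conversion rate: ", format(object@conversionRate, digits = 6), "\n",
      "  cytosines: ", nrow(object@sites), " (",
      paste(names(table(object@sites$context)),
            table(object@sites$context), sep = ":", collapse = " "), ")\n",
      sep = "")
})

#' @describeIn MethylomeSample-class accessor for the sample identifier.
#' @param object a `MethylomeSample`.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname MethylomeSample-class
#' @export
setMethod("sampleId", "MethylomeSample", function(object) object@sampleId)

#' @describeIn MethylomeSample-class accessor for the species name.
#' @export
setGeneric("speciesName", function(object) standardGeneric("speciesName"))

#' @rdname MethylomeSample-class
#' @export
setMethod("speciesName", "MethylomeSample", function(object) object@species)

#' @describeIn MethylomeSample-class accessor for the conversion rate.
#' @export
setGeneric("conversionRate", function(object) standardGeneric("conversionRate"))

#' @rdname MethylomeSample-class
#' @export
setMethod("conversionRate", "MethylomeSample", function(object) object@conversionRate)

#' @describeIn MethylomeSample-class accessor for the cytosine table.
#' @export
setGeneric("siteTable", function(object) standardGeneric("siteTable"))

#' @rdname MethylomeSample-class
#' @export
setMethod("siteTable", "MethylomeSample", function(object) object@sites)

#' The species-pair phylogeny
#'
#' A rooted tree whose ingroup is organised as species pairs (one mangrove,
#' one non-mangrove ecological counterpart) plus a single outgroup leaf
#' attached at the root. The packaged default is the seven-taxon design
#' `(Osa,((Ama,Mgu),((Rap,Ptr),(Sal,Egr))))` with rice as outgroup.
#'
#' @slot tree an `ape::phylo`, rooted, with the outgroup as a direct child
#'   of the root.
#' @slot roles named character vector leaf -> mangrove/nonmangrove/outgroup.
#' @export
setClass("SpeciesPairTree",
         representation(tree = "ANY", roles = "character"),
         validity = function(object) {
  msg <- character(0)
  tr <- object@tree
  if (!inherits(tr, "phylo")) return("tree must be an ape phylo object")
  if (!setequal(tr$tip.label, names(object@roles)))
    msg <- c(msg, "roles must name exactly the tree's tips")
  if (sum(object@roles == "outgroup") != 1L)
    msg <- c(msg, "exactly one outgroup leaf required")
  if (length(msg)) msg else TRUE
})

#' Construct a SpeciesPairTree
#'
#' @param tree an `ape::phylo` rooted tree with the outgroup attached at the
#'   root, or a Newick string.
#' @param roles named character vector mapping each tip to
#'   mangrove/nonmangrove/outgroup.
#' @return a `SpeciesPairTree`.
#' @examples
#' speciesPairTree()
#' @export
speciesPairTree <- function(tree = defaultSpeciesTree(),
                            roles = defaultSpeciesRoles()) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  new("SpeciesPairTree", tree = tree, roles = roles)
}

setMethod("show", "SpeciesPairTree", function(object) {
  cat("SpeciesPairTree with", length(object@tree$tip.label), "tips\n")
  cat("  mangroves:   ",
      paste(names(object@roles)[object@roles == "mangrove"], collapse = ", "), "\n")
  cat("  nonmangroves:",
      paste(names(object@roles)[object@roles == "nonmangrove"], collapse = ", "), "\n")
  cat("  outgroup:    ",
      names(object@roles)[object@roles == "outgroup"], "\n")
})

#' Default seven-taxon species tree
#'
#' Topology `(Osa,((Ama,Mgu)P1,((Rap,Ptr)P2,(Sal,Egr)P3)Ninner)Root)`: three
#' mangrove/non-mangrove pairs (Avicennia marina / Mimulus guttatus,
#' Rhizophora apiculata / Populus trichocarpa, Sonneratia alba / Eucalyptus
#' grandis) with Oryza sativa as outgroup.
#'
#' @return an `ape::phylo` with labelled internal nodes.
#' @export
defaultSpeciesTree <- function() {
  ape::read.tree(
    text = "(Osa,((Ama,Mgu)P1,((Rap,Ptr)P2,(Sal,Egr)P3)Ninner)Root)R;")
}

#' Default species roles for the seven-taxon design
#'
#' @return named character vector mapping species codes to roles.
#' @export
defaultSpeciesRoles <- function() {
  c(Ama = "mangrove", Rap = "mangrove", Sal = "mangrove",
    Mgu = "nonmangrove", Ptr = "nonmangrove", Egr = "nonmangrove",
    Osa = "outgroup")
}
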
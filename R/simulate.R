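# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth: planted body-methylated genes,
# tree-structured gbM evolution with forced convergence, salt-induced gbM
# gains enriched in convergent genes, and variance-buffered expression.
# Counts are simulated directly (coverage ~ Poisson, methylated reads ~
# Binomial); the pipeline never sees reads.

contextTrinucleotide <- c(CG = "CGA", CHG = "CAG", CHH = "CAT")

# lay out genes head to tail on one chromosome and draw per-site truth
buildGeneSites <- function(n_genes, sites_per_gene, gap = 50L) {
  per_gene <- lapply(seq_len(n_genes), function(g) {
    counts <- vapply(sites_per_gene, function(lam) stats::rpois(1L, lam),
                     integer(1))
    rep(names(sites_per_gene), counts)
  })
  n_sites <- lengths(per_gene)
  gene_end <- cumsum(n_sites + gap)
  gene_start <- gene_end - n_sites - gap + 1L
  data.frame(
    gene_id = rep(sprintf("gene%05d", seq_len(n_genes)), n_sites),
    pos = unlist(lapply(seq_len(n_genes),
                        function(g) seq(gene_start[g],
                                        length.out = n_sites[g]))),
    context = unlist(per_gene),
    stringsAsFactors = FALSE)
}

geneRangesFromSites <- function(site_table) {
  lo <- vapply(split(site_table$pos, site_table$gene_id), min, numeric(1))
  hi <- vapply(split(site_table$pos, site_table$gene_id), max, numeric(1))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(lo, hi), strand = "+",
                               gene_id = names(lo))
  grl <- GenomicRanges::split(gr, gr$gene_id)
  S4Vectors::mcols(grl)$gene_id <- names(grl)
  S4Vectors::mcols(grl)$transcript_id <- paste0(names(grl), ".1")
  grl
}

drawSampleCounts <- function(truth_state, coverage_mean, methylated_read_level,
                             conversion_rate) {
  n <- length(truth_state)
  coverage <- stats::rpois(n, coverage_mean)
  err <- 1 - conversion_rate
  # err + state * (level + (1 - level) * err - err), vectorised
  p_read <- err + truth_state * methylated_read_level * (1 - err)
  meth <- stats::rbinom(n, coverage, p_read)
  list(meth = meth, unmeth = coverage - meth)
}

siteReport <- function(site_table, meth, unmeth) {
  data.frame(chrom = "chr1", pos = site_table$pos, strand = "+",
             count_meth = meth, count_unmeth = unmeth,
             context = site_table$context,
             trinucleotide = unname(contextTrinucleotide[site_table$context]),
             stringsAsFactors = FALSE)
}

#' Simulate a replicated methylome with planted body-methylated genes
#'
#' Genes are laid head to tail on one chromosome, each with a Poisson number
#' of cytosines per context inside its CDS, plus free-standing intergenic
#' cytosines. A planted fraction of genes is body-methylated: their CG sites
#' are truly methylated with probability `bmSiteLevel`; every other site is
#' methylated with its context's background probability. Site truth is drawn
#' once and shared by all replicates; per replicate, coverage is Poisson and
#' methylated reads binomial with per-read probability
#' `level + (1 - level) * (1 - conversionRate)` at truly methylated sites and
#' `1 - conversionRate` elsewhere.
#'
#' @param nGenes number of genes (default 2000).
#' @param sitesPerGene named Poisson means for cytosines per context within
#'   a gene (default 40 each, comfortably above the 20-site classification
#'   floor).
#' @param background per-context probability that a non-planted site is
#'   truly methylated (default CG 0.15, CHG 0.10, CHH 0.05).
#' @param bmGeneFraction fraction of genes planted as body-methylated
#'   (default 0.15).
#' @param bmSiteLevel probability that a CG site of a planted gene is truly
#'   methylated (default 0.8).
#' @param methylatedReadLevel per-read methylation probability at a truly
#'   methylated site (default 0.8).
#' @param coverageMean Poisson mean read depth per site per replicate
#'   (default 20).
#' @param conversionRate bisulfite conversion rate (default 0.995).
#' @param nReplicates number of replicate libraries (default 3).
#' @param intergenicSites named counts of intergenic cytosines per context
#'   (default 5000 each).
#' @param species species label for the generated samples.
#' @param seed integer seed; the output is reproducible given the seed.
#' @return list: `samples` (list of [MethylomeSample-class]), `genes`
#'   (`GRangesList` of CDS per gene), `truth` (list with `bm_genes`,
#'   per-gene table and per-site states) and `params`.
#' @export
simulateMethylome <- function(nGenes = 2000L,
                              sitesPerGene = c(CG = 40, CHG = 40, CHH = 40),
                              background = c(CG = 0.15, CHG = 0.10, CHH = 0.05),
                              bmGeneFraction = 0.15, bmSiteLevel = 0.8,
                              methylatedReadLevel = 0.8, coverageMean = 20,
                              conversionRate = 0.995, nReplicates = 3L,
                              intergenicSites = c(CG = 5000, CHG = 5000,
                                                  CHH = 5000),
                              species = "SimulatedSp", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genic <- buildGeneSites(nGenes, sitesPerGene)
  inter <- data.frame(
    gene_id = NA_character_,
    pos = max(genic$pos) + 1000L + seq_len(sum(intergenicSites)),
    context = rep(names(intergenicSites), intergenicSites),
    stringsAsFactors = FALSE)
  sites <- rbind(genic, inter)

  gene_ids <- unique(genic$gene_id)
  is_bm_gene <- stats::runif(length(gene_ids)) < bmGeneFraction
  names(is_bm_gene) <- gene_ids
  p_true <- background[sites$context]
  planted <- !is.na(sites$gene_id) & is_bm_gene[sites$gene_id] &
    sites$context == "CG"
  p_true[planted] <- bmSiteLevel
  truth_state <- stats::runif(nrow(sites)) < p_true

  samples <- lapply(seq_len(nReplicates), function(r) {
    cnt <- drawSampleCounts(truth_state, coverageMean, methylatedReadLevel,
                            conversionRate)
    methylomeSample(sprintf("%s_rep%d", species, r), species, conversionRate,
                    siteReport(sites, cnt$meth, cnt$unmeth))
  })
  list(samples = samples,
       genes = geneRangesFromSites(genic),
       truth = list(
         bm_genes = gene_ids[is_bm_gene],
         genes = data.frame(gene_id = gene_ids, planted_bm = unname(is_bm_gene),
                            stringsAsFactors = FALSE),
         sites = data.frame(pos = sites$pos, context = sites$context,
                            gene_id = sites$gene_id,
                            methylated = truth_state,
                            stringsAsFactors = FALSE)),
       params = list(nGenes = nGenes, sitesPerGene = sitesPerGene,
                     background = background, bmGeneFraction = bmGeneFraction,
                     bmSiteLevel = bmSiteLevel,
                     methylatedReadLevel = methylatedReadLevel,
                     coverageMean = coverageMean,
                     conversionRate = conversionRate, seed = seed))
}

#' Simulate gbM states evolving along the species tree
#'
#' Root states are Bernoulli draws; along every branch a UM lineage gains
#' gbM with probability `gainProb` and a BM lineage loses it with
#' probability `lossProb`. On top of the neutral process, a fraction of
#' root-UM clusters receives forced convergent BM states in two or three
#' mangrove leaves (two with probability 0.68, mirroring the observed
#' two-vs-three split).
#'
#' @param nClusters number of 1:1 ortholog clusters (default 7343).
#' @param spt a [SpeciesPairTree-class].
#' @param rootBmFraction probability of BM at the root (default 743/7343,
#'   the ancestrally body-methylated fraction of the cluster set).
#' @param gainProb,lossProb per-branch change probabilities.
#' @param convergentFraction fraction of root-UM clusters given forced
#'   mangrove convergence (default 0.05).
#' @param seed integer seed.
#' @return list: `leafStates` (clusters x species matrix of "BM"/"UM"),
#'   `truth` (per-cluster root state, forced flag, number of forced
#'   mangrove leaves) and `params`.
#' @export
simulateTreeStates <- function(nClusters = 7343L, spt = speciesPairTree(),
                               rootBmFraction = 743 / 7343,
                               gainProb = 0.02, lossProb = 0.005,
                               convergentFraction = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- stats::reorder(spt@tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- matrix(NA, nClusters, ntip + tree$Nnode)
  states[, root] <- stats::runif(nClusters) < rootBmFraction   # TRUE = BM
  edge <- tree$edge
  for (e in rev(seq_len(nrow(edge)))) {   # preorder
    p <- states[, edge[e, 1L]]
    flip_gain <- !p & stats::runif(nClusters) < gainProb
    flip_loss <- p & stats::runif(nClusters) < lossProb
    states[, edge[e, 2L]] <- (p | flip_gain) & !flip_loss
  }
  leaf <- states[, seq_len(ntip), drop = FALSE]
  colnames(leaf) <- tree$tip.label

  mang <- names(spt@roles)[spt@roles == "mangrove"]
  root_um <- !states[, root]
  forced <- root_um & stats::runif(nClusters) < convergentFraction
  n_forced <- integer(nClusters)
  if (any(forced)) {
    n_forced[forced] <- ifelse(stats::runif(sum(forced)) < 0.68, 2L, 3L)
    for (i in which(forced)) {
      pick <- sample(mang, n_forced[i])
      leaf[i, pick] <- TRUE
    }
  }
  cluster_id <- sprintf("cluster%05d", seq_len(nClusters))
  leaf_chr <- ifelse(leaf, "BM", "UM")
  dimnames(leaf_chr) <- list(cluster_id, tree$tip.label)
  list(leafStates = leaf_chr,
       truth = data.frame(cluster_id = cluster_id,
                          root_state = ifelse(states[, root], "BM", "UM"),
                          forced_convergent = forced,
                          n_forced_mangroves = n_forced,
                          stringsAsFactors = FALSE),
       params = list(nClusters = nClusters, rootBmFraction = rootBmFraction,
                     gainProb = gainProb, lossProb = lossProb,
                     convergentFraction = convergentFraction, seed = seed))
}

#' Simulate a salt-treatment experiment with known truth
#'
#' Generates the full treated/control design: a control methylome (genes
#' body-methylated according to their baseline class), a treated methylome
#' in which baseline-UM genes gain gbM with a probability that depends on
#' their convergence label (convBMM genes preferentially) and baseline-BM
#' genes lose it with probability `lossProb`, three replicate libraries per
#' condition, and an expression count matrix in which the treatment response
#' of a gene is drawn with a standard deviation set by its regime: genes
#' body-methylated under treatment are variance-buffered, the rest are not.
#'
#' @param nGenes number of genes (default 2500).
#' @param convbmmFraction fraction of genes carrying the convBMM label
#'   (default 0.1).
#' @param baselineBmFraction fraction of genes body-methylated at baseline
#'   (default 0.15).
#' @param gainProbByGroup named probabilities of salt-induced gbM gain for
#'   baseline-UM genes (default convBMM 0.12, other 0.01, the planted
#'   contrast).
#' @param lossProb probability of salt-induced gbM loss for baseline-BM
#'   genes (default 0.01).
#' @param sitesPerGene,background,bmSiteLevel,methylatedReadLevel,coverageMean,conversionRate,nReplicates
#'   methylome parameters as in [simulateMethylome()].
#' @param responseSdByRegime named standard deviations of the log10
#'   treatment response (default buffered 0.05, unbuffered 0.3: roughly
#'   two-fold expression swings for unbuffered genes, near-flat response
#'   for buffered ones, in line with the overall transcriptional
#'   robustness of the system).
#' @param baseLog10Mean,baseLog10Sd log10 mean expression distribution.
#' @param dispersion gamma dispersion of the Poisson-gamma counts.
#' @param seed integer seed.
#' @return list with `control`/`treated` (lists of [MethylomeSample-class]),
#'   `genes`, `counts` (genes x 6 matrix), `conditions`, `geneLengths`,
#'   `truth` (per-gene label, baseline class, induced gain/loss, regime)
#'   and `params`.
#' @export
simulateSaltExperiment <- function(nGenes = 2500L, convbmmFraction = 0.1,
                                   baselineBmFraction = 0.15,
                                   gainProbByGroup = c(convBMM = 0.12,
                                                       other = 0.01),
                                   lossProb = 0.01,
                                   sitesPerGene = c(CG = 40, CHG = 40,
                                                    CHH = 40),
                                   background = c(CG = 0.15, CHG = 0.10,
                                                  CHH = 0.05),
                                   bmSiteLevel = 0.8,
                                   methylatedReadLevel = 0.8,
                                   coverageMean = 20, conversionRate = 0.995,
                                   nReplicates = 3L,
                                   responseSdByRegime = c(buffered = 0.05,
                                                          unbuffered = 0.3),
                                   baseLog10Mean = 1.5, baseLog10Sd = 0.4,
                                   dispersion = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genic <- buildGeneSites(nGenes, sitesPerGene)
  gene_ids <- unique(genic$gene_id)
  n <- length(gene_ids)
  label <- ifelse(stats::runif(n) < convbmmFraction, "convBMM", "other")
  baseline_bm <- stats::runif(n) < baselineBmFraction
  gain <- !baseline_bm & stats::runif(n) < gainProbByGroup[label]
  loss <- baseline_bm & stats::runif(n) < lossProb
  bm_treated <- (baseline_bm & !loss) | gain

  site_p <- function(bm_by_gene) {
    p <- background[genic$context]
    planted <- bm_by_gene[genic$gene_id] & genic$context == "CG"
    p[planted] <- bmSiteLevel
    p
  }
  truth_ctrl <- stats::runif(nrow(genic)) <
    site_p(stats::setNames(baseline_bm, gene_ids))
  truth_trt <- truth_ctrl
  redraw <- gene_ids[gain | loss]
  redraw_sites <- genic$gene_id %in% redraw
  p_trt <- site_p(stats::setNames(bm_treated, gene_ids))
  truth_trt[redraw_sites] <- stats::runif(sum(redraw_sites)) <
    p_trt[redraw_sites]

  makeReps <- function(truth_state, cond) {
    lapply(seq_len(nReplicates), function(r) {
      cnt <- drawSampleCounts(truth_state, coverageMean, methylatedReadLevel,
                              conversionRate)
      methylomeSample(sprintf("%s_rep%d", cond, r), "SimulatedSp",
                      conversionRate, siteReport(genic, cnt$meth, cnt$unmeth))
    })
  }
  control <- makeReps(truth_ctrl, "control")
  treated <- makeReps(truth_trt, "treated")

  regime <- ifelse(bm_treated, "buffered", "unbuffered")
  gene_len <- round(stats::runif(n, 500, 3000))
  base_mu <- 10^stats::rnorm(n, baseLog10Mean, baseLog10Sd)
  response <- stats::rnorm(n, 0, responseSdByRegime[regime])
  conditions <- rep(c("control", "treated"), each = nReplicates)
  counts <- sapply(seq_along(conditions), function(s) {
    mu <- base_mu * (gene_len / 1000) *
      (if (conditions[s] == "treated") 10^response else 1)
    stats::rpois(n, mu * stats::rgamma(n, shape = 1 / dispersion,
                                       scale = dispersion))
  })
  dimnames(counts) <- list(gene_ids,
                           paste(conditions, rep(1:nReplicates, 2L),
                                 sep = "_"))
  list(control = control, treated = treated,
       genes = geneRangesFromSites(genic), counts = counts,
       conditions = conditions,
       geneLengths = stats::setNames(gene_len, gene_ids),
       truth = data.frame(gene_id = gene_ids, label = label,
                          baseline_class = ifelse(baseline_bm, "BM", "UM"),
                          induced_gain = gain, induced_loss = loss,
                          regime = regime, stringsAsFactors = FALSE),
       params = list(nGenes = nGenes, convbmmFraction = convbmmFraction,
                     baselineBmFraction = baselineBmFraction,
                     gainProbByGroup = gainProbByGroup, lossProb = lossProb,
                     responseSdByRegime = responseSdByRegime, seed = seed))
}
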
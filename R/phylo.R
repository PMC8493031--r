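# Ancestral gbM state inference and the convergence classifier.
#
# The reconstruction is hierarchical parsimony on the ingroup (the three
# species pairs): Fitch candidate sets are built bottom-up from each pair's
# leaves towards the pair ancestors, the inner node joining two pairs, and
# the ingroup root. Whenever the root's candidate set remains ambiguous
# ({BM, UM}), the outgroup (rice) leaf state is taken as the ancestral
# state. A top-down pass then resolves every internal node: a node adopts
# its parent's state when that state is among its candidates, otherwise its
# sole candidate. States are encoded as bits (1 = UM, 2 = BM, 3 = both).

STATE_UM <- 1L
STATE_BM <- 2L

encodeStates <- function(x) {
  out <- ifelse(x == "BM", STATE_BM, ifelse(x == "UM", STATE_UM, NA_integer_))
  if (any(is.na(out))) stop("states must be 'BM' or 'UM'")
  out
}

decodeStates <- function(x) c("UM", "BM", "BM/UM")[x]

ingroupTree <- function(spt) {
  outgroup <- names(spt@roles)[spt@roles == "outgroup"]
  ig <- ape::drop.tip(spt@tree, outgroup)
  stats::reorder(ig, "postorder")
}

nodeLabelsOf <- function(tree) {
  ntip <- length(tree$tip.label)
  labs <- tree$node.label
  if (is.null(labs) || !length(labs) || any(labs == ""))
    labs <- paste0("node", seq_len(tree$Nnode) + ntip)
  c(tree$tip.label, labs)
}

#' Infer ancestral gbM states by hierarchical parsimony
#'
#' Maximum-parsimony reconstruction of the BM/UM state at every internal
#' node of the ingroup, with the outgroup state resolving ties at the root
#' (the outgroup is used only as a tie-breaker, never as part of the Fitch
#' pass). Clusters with a missing leaf state are skipped with a warning.
#'
#' @param leafStates matrix (clusters x species) or named vector (one
#'   cluster) of "BM"/"UM"; column names must cover every tree leaf,
#'   including the outgroup. Row names are taken as cluster ids.
#' @param spt a [SpeciesPairTree-class].
#' @return object of class `AncestralAssignment`: a list with
#'   `states` (clusters x nodes matrix of "BM"/"UM", tips then internal
#'   nodes), `rootState`, `resolvedByOutgroup`, `candidates` (Fitch
#'   candidate codes), `leafStates` (the input, including the outgroup),
#'   `tree` (the postorder ingroup phylo) and `cluster_id`.
#' @export
inferAncestralStates <- function(leafStates, spt = speciesPairTree()) {
  if (is.null(dim(leafStates)))
    leafStates <- matrix(leafStates, nrow = 1L,
                         dimnames = list("cluster1", names(leafStates)))
  stopifnot(all(spt@tree$tip.label %in% colnames(leafStates)))
  cluster_id <- rownames(leafStates)
  if (is.null(cluster_id)) cluster_id <- paste0("cluster", seq_len(nrow(leafStates)))
  complete <- stats::complete.cases(leafStates[, spt@tree$tip.label, drop = FALSE])
  if (!all(complete)) {
    warning(sum(!complete), " cluster(s) with missing leaf states skipped")
    leafStates <- leafStates[complete, , drop = FALSE]
    cluster_id <- cluster_id[complete]
  }
  ig <- ingroupTree(spt)
  ntip <- length(ig$tip.label)
  nnode <- ig$Nnode
  ncl <- nrow(leafStates)
  edge <- ig$edge

  cand <- matrix(0L, ncl, ntip + nnode)
  for (i in seq_len(ntip))
    cand[, i] <- encodeStates(leafStates[, ig$tip.label[i]])
  for (n in unique(edge[, 1L])) {          # postorder: children before parents
    kids <- edge[edge[, 1L] == n, 2L]
    acc <- cand[, kids[1L]]
    for (k in kids[-1L]) {
      inter <- bitwAnd(acc, cand[, k])
      acc <- ifelse(inter > 0L, inter, bitwOr(acc, cand[, k]))
    }
    cand[, n] <- acc
  }

  root <- ntip + 1L
  outgroup <- names(spt@roles)[spt@roles == "outgroup"]
  out_state <- encodeStates(leafStates[, outgroup])
  resolved_by_outgroup <- cand[, root] == 3L
  states <- matrix(0L, ncl, ntip + nnode)
  states[, seq_len(ntip)] <- cand[, seq_len(ntip)]
  states[, root] <- ifelse(resolved_by_outgroup, out_state, cand[, root])
  for (e in rev(seq_len(nrow(edge)))) {    # preorder: parents before children
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    if (ch <= ntip) next
    sp <- states[, p]
    states[, ch] <- ifelse(bitwAnd(cand[, ch], sp) > 0L, sp, cand[, ch])
  }

  labs <- nodeLabelsOf(ig)
  dimnames(states) <- list(cluster_id, labs)
  dimnames(cand) <- list(cluster_id, labs)
  structure(list(states = matrix(decodeStates(states), ncl,
                                 dimnames = dimnames(states)),
                 rootState = decodeStates(states[, root]),
                 resolvedByOutgroup = resolved_by_outgroup,
                 candidates = cand,
                 leafStates = leafStates[, spt@tree$tip.label, drop = FALSE],
                 tree = ig, cluster_id = cluster_id),
            class = "AncestralAssignment")
}

#' @export
print.AncestralAssignment <- function(x, ...) {
  cat("AncestralAssignment for", length(x$cluster_id), "cluster(s);",
      sum(x$resolvedByOutgroup), "root tie(s) resolved by the outgroup\n")
  invisible(x)
}

#' Count gbM gains and losses per branch
#'
#' For every ingroup branch, the number of clusters whose state flips from
#' UM at the parent to BM at the child (a gain) or from BM to UM (a loss),
#' together with the number of UM and BM clusters at the parent node --
#' the denominators of the per-branch rates.
#'
#' @param assignment an `AncestralAssignment` from [inferAncestralStates()].
#' @return data.frame, one row per branch: parent, child, gains, losses,
#'   parent_um, parent_bm.
#' @export
countGainLoss <- function(assignment) {
  tree <- assignment$tree
  labs <- nodeLabelsOf(tree)
  st <- assignment$states
  edge <- tree$edge
  rows <- lapply(seq_len(nrow(edge)), function(e) {
    p <- labs[edge[e, 1L]]; ch <- labs[edge[e, 2L]]
    sp <- st[, p]; sc <- st[, ch]
    data.frame(parent = p, child = ch,
               gains = sum(sp == "UM" & sc == "BM"),
               losses = sum(sp == "BM" & sc == "UM"),
               parent_um = sum(sp == "UM"), parent_bm = sum(sp == "BM"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-branch gbM gain and loss rates
#'
#' The maximum-likelihood estimate of the per-branch change probability:
#' lineage-specific gains divided by the UM count at the parent node, and
#' losses divided by the BM count. Undefined (NA) when the denominator is
#' zero.
#'
#' @param branchTable data.frame from [countGainLoss()].
#' @return the same table with columns gain_rate and loss_rate appended.
#' @export
gainLossRates <- function(branchTable) {
  branchTable$gain_rate <- ifelse(branchTable$parent_um > 0,
                                  branchTable$gains / branchTable$parent_um,
                                  NA_real_)
  branchTable$loss_rate <- ifelse(branchTable$parent_bm > 0,
                                  branchTable$losses / branchTable$parent_bm,
                                  NA_real_)
  branchTable
}

#' Classify convergent gbM gains
#'
#' The convergence-at-conserved-sites rule applied to gene states: a cluster
#' is convergently body-methylated in mangroves (convBMM) when the
#' reconstructed ancestral (ingroup root) state is UM and at least two of
#' the three mangrove leaves carry the derived BM state; convBMN is the
#' mirror condition for the non-mangrove species. A cluster that is BM in
#' at least two species without satisfying either condition is non-convBM;
#' anything else is "none". The conservation group is the number of species
#' (out of all leaves, outgroup included) in which the gene is BM.
#'
#' @param assignment an `AncestralAssignment` from [inferAncestralStates()].
#' @param roles named character vector of species roles (defaults to the
#'   roles used for the packaged seven-taxon design).
#' @return data.frame: cluster_id, root_state, label
#'   (convBMM/convBMN/non-convBM/none), n_bm_mangrove, n_bm_nonmangrove,
#'   conservation_group.
#' @export
classifyConvergence <- function(assignment, roles = defaultSpeciesRoles()) {
  leaf <- assignment$leafStates
  mang <- names(roles)[roles == "mangrove"]
  nonm <- names(roles)[roles == "nonmangrove"]
  stopifnot(all(c(mang, nonm) %in% colnames(leaf)))
  n_bm_m <- rowSums(leaf[, mang, drop = FALSE] == "BM")
  n_bm_n <- rowSums(leaf[, nonm, drop = FALSE] == "BM")
  n_bm_all <- rowSums(leaf == "BM")
  root_um <- assignment$rootState == "UM"
  label <- rep("none", nrow(leaf))
  label[n_bm_all >= 2L] <- "non-convBM"
  label[root_um & n_bm_n >= 2L] <- "convBMN"
  label[root_um & n_bm_m >= 2L] <- "convBMM"
  data.frame(cluster_id = assignment$cluster_id,
             root_state = assignment$rootState, label = label,
             n_bm_mangrove = n_bm_m, n_bm_nonmangrove = n_bm_n,
             conservation_group = n_bm_all,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Convergence of methylation at individual conserved CG sites
#'
#' The gene-level machinery applied to the methylation status of CG sites
#' conserved across all species: "methylated" plays the role of BM and
#' "unmethylated" of UM. Sites missing a species are excluded and counted.
#'
#' @param siteStates matrix (sites x species) of "methylated"/"unmethylated"
#'   (NA allowed; such sites are excluded).
#' @param spt a [SpeciesPairTree-class].
#' @param roles species roles (defaults match `spt`'s packaged default).
#' @return list with `labels` (the [classifyConvergence()] data.frame, with
#'   convBMM meaning mangrove-convergent methylation gain) and `n_excluded`.
#' @export
siteConvergence <- function(siteStates, spt = speciesPairTree(),
                            roles = defaultSpeciesRoles()) {
  stopifnot(all(siteStates %in% c("methylated", "unmethylated", NA)))
  complete <- stats::complete.cases(siteStates)
  excluded <- sum(!complete)
  x <- siteStates[complete, , drop = FALSE]
  mapped <- ifelse(x == "methylated", "BM", "UM")
  dimnames(mapped) <- dimnames(x)
  assignment <- inferAncestralStates(mapped, spt)
  list(labels = classifyConvergence(assignment, roles), n_excluded = excluded)
}

#' Summarise convergence labels
#'
#' Counts and percentages (of all clusters) for each convergence category,
#' with convBMM split by whether two or all three mangroves carry the
#' derived BM state.
#'
#' @param labels data.frame from [classifyConvergence()].
#' @return data.frame with category, n and pct (percentage of the total
#'   cluster count, one decimal).
#' @export
summarizeConvergence <- function(labels) {
  total <- nrow(labels)
  cats <- list(
    convBMM_two_species = labels$label == "convBMM" & labels$n_bm_mangrove == 2L,
    convBMM_three_species = labels$label == "convBMM" & labels$n_bm_mangrove == 3L,
    convBMN_two_species = labels$label == "convBMN" & labels$n_bm_nonmangrove == 2L,
    convBMN_three_species = labels$label == "convBMN" & labels$n_bm_nonmangrove == 3L,
    non_convBM = labels$label == "non-convBM",
    none = labels$label == "none")
  data.frame(category = names(cats),
             n = vapply(cats, sum, integer(1)),
             pct = vapply(cats, function(i) round(100 * sum(i) / total, 1),
                          numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stability of gbM status between two gene classifications
#'
#' The fraction of genes body-methylated under a reference classification
#' (e.g. plants sampled in nature) that are also body-methylated under a
#' comparison classification (e.g. freshwater-grown control seedlings).
#'
#' @param reference,comparison named character vectors of gene classes
#'   (names are gene ids; values as in [classifyGenes()]).
#' @return list with `shared`, `total` (reference BM genes also present in
#'   the comparison) and `pct` (one decimal).
#' @export
gbmStability <- function(reference, comparison) {
  bm <- names(reference)[reference == "BM"]
  bm <- bm[bm %in% names(comparison)]
  shared <- sum(comparison[bm] == "BM")
  list(shared = shared, total = length(bm),
       pct = round(100 * shared / length(bm), 1))
}
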
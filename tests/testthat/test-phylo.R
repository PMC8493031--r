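SPECIES7 <- c("Ama", "Mgu", "Rap", "Ptr", "Sal", "Egr", "Osa")

stateVec <- function(bm_species) {
  out <- setNames(rep("UM", 7), SPECIES7)
  out[bm_species] <- "BM"
  out
}

test_that("hierarchical parsimony resolves the canonical patterns", {
  # all leaves BM: everything BM, zero changes
  a <- inferAncestralStates(stateVec(SPECIES7))
  expect_true(all(a$states == "BM"))
  expect_equal(impliedChanges(a), 0)
  # mangroves BM, everything else UM: root UM via the outgroup tie rule,
  # three independent terminal gains
  b <- inferAncestralStates(stateVec(c("Ama", "Rap", "Sal")))
  expect_equal(b$rootState, "UM")
  expect_true(b$resolvedByOutgroup)
  expect_equal(impliedChanges(b), 3)
  bt <- countGainLoss(b)
  expect_equal(sum(bt$gains), 3)
  expect_equal(bt$gains[bt$child %in% c("Ama", "Rap", "Sal")], rep(1L, 3))
  expect_equal(sum(bt$losses), 0)
  # two full pairs BM: root BM without consulting the outgroup
  cc <- inferAncestralStates(stateVec(c("Ama", "Mgu", "Rap", "Ptr")))
  expect_equal(cc$rootState, "BM")
  expect_false(cc$resolvedByOutgroup)
  expect_equal(cc$states[1, "P1"], "BM")
  expect_equal(cc$states[1, "P3"], "UM")
  oracle <- parsimonyOracle(
    setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
             c("Ama", "Mgu", "Rap", "Ptr", "Sal", "Egr")), osa = FALSE)
  expect_equal(impliedChanges(cc), oracle$min_changes)
  # missing leaf state: cluster skipped with a warning
  m <- rbind(stateVec("Ama"), stateVec("Rap"))
  m[2, "Osa"] <- NA
  expect_warning(d <- inferAncestralStates(m), "skipped")
  expect_equal(length(d$cluster_id), 1)
})

test_that("resolved assignments reach the exhaustive parsimony minimum on all 128 leaf patterns", {
  ing <- c("Ama", "Mgu", "Rap", "Ptr", "Sal", "Egr")
  for (mask in 0:127) {
    bits <- as.logical(bitwAnd(mask, 2^(0:6)))
    leaves <- setNames(bits[1:6], ing)
    osa <- bits[7]
    lv <- setNames(ifelse(c(bits[1:6], osa), "BM", "UM"), c(ing, "Osa"))
    a <- inferAncestralStates(lv)
    o <- parsimonyOracle(leaves, osa)
    expect_equal((a$rootState == "BM"), o$root,
                 info = paste("root for mask", mask))
    expect_equal(a$resolvedByOutgroup, o$tie)
    expect_equal(impliedChanges(a), o$min_changes,
                 info = paste("changes for mask", mask))
    # without a tie the resolution attains the unconstrained minimum
    if (!o$tie) expect_equal(o$min_changes, o$overall_min)
  }
})

test_that("convergence labels match the truth-table oracle on all 128 patterns", {
  ing <- c("Ama", "Mgu", "Rap", "Ptr", "Sal", "Egr")
  for (mask in 0:127) {
    bits <- as.logical(bitwAnd(mask, 2^(0:6)))
    lv <- setNames(ifelse(bits, "BM", "UM"), c(ing, "Osa"))
    a <- inferAncestralStates(lv)
    lab <- classifyConvergence(a)
    o <- convergenceOracle(setNames(bits[1:6], ing), bits[7],
                           root = (a$rootState == "BM"))
    # both conditions can only coincide when two full pairs are BM and the
    # root tie falls to the outgroup; the mangrove label takes precedence
    if (o$both) expect_equal(sum(bits[1:6]), 4)
    expect_equal(lab$label, o$label, info = paste("mask", mask))
    expect_equal(lab$conservation_group, o$group)
  }
  # spec'd single cases
  lab1 <- classifyConvergence(inferAncestralStates(stateVec(c("Ama", "Rap", "Sal"))))
  expect_equal(lab1$label, "convBMM")
  expect_equal(lab1$conservation_group, 3)
  lab2 <- classifyConvergence(inferAncestralStates(stateVec(character(0))))
  expect_equal(lab2$label, "none")
  lab3 <- classifyConvergence(inferAncestralStates(stateVec(c("Ama", "Ptr"))))
  expect_equal(lab3$label, "non-convBM")
  expect_equal(lab3$conservation_group, 2)
})

test_that("gain/loss bookkeeping is consistent across branches", {
  sim <- simulateTreeStates(nClusters = 500, seed = 61)
  a <- inferAncestralStates(sim$leafStates)
  tab <- countGainLoss(a)
  expect_true(all(tab$gains <= tab$parent_um))
  expect_true(all(tab$losses <= tab$parent_bm))
  expect_true(all(tab$parent_um + tab$parent_bm == 500))
  rates <- gainLossRates(tab)
  expect_true(all(rates$gain_rate >= 0 & rates$gain_rate <= 1, na.rm = TRUE))
  # per cluster, net BM difference between child and parent equals
  # gains - losses summed over branches
  labs <- colnames(a$states)
  edge <- a$tree$edge
  per_branch_net <- sum(tab$gains) - sum(tab$losses)
  net_direct <- sum(vapply(seq_len(nrow(edge)), function(e) {
    sum((a$states[, labs[edge[e, 2]]] == "BM") -
          (a$states[, labs[edge[e, 1]]] == "BM"))
  }, numeric(1)))
  expect_equal(per_branch_net, net_direct)
})

test_that("branch rates recover the planted gain and loss probabilities", {
  sim <- simulateTreeStates(nClusters = 10000, gainProb = 0.02,
                            lossProb = 0.01, convergentFraction = 0,
                            seed = 62)
  a <- inferAncestralStates(sim$leafStates)
  rates <- gainLossRates(countGainLoss(a))
  # terminal branches sit farthest from the root and carry the least
  # reconstruction bias; pool them and check a 95% binomial CI
  term <- rates[rates$child %in% c("Ama", "Mgu", "Rap", "Ptr", "Sal", "Egr"), ]
  ci_gain <- binom.test(sum(term$gains), sum(term$parent_um))$conf.int
  expect_true(ci_gain[1] <= 0.02 && 0.02 <= ci_gain[2])
  ci_loss <- binom.test(sum(term$losses), sum(term$parent_bm))$conf.int
  expect_true(ci_loss[1] <= 0.01 && 0.01 <= ci_loss[2])
})

test_that("site-level convergence shares the gene-level machinery", {
  set.seed(63)
  n <- 50
  m <- matrix(sample(c("methylated", "unmethylated"), n * 7, replace = TRUE),
              n, 7, dimnames = list(NULL, SPECIES7))
  m[1, ] <- c("methylated", "unmethylated", "methylated", "unmethylated",
              "methylated", "unmethylated", "unmethylated")
  m[2, ] <- rep("methylated", 7)
  m[3, "Osa"] <- NA
  res <- suppressWarnings(siteConvergence(m))
  expect_equal(res$n_excluded, 1)
  expect_equal(res$labels$label[1], "convBMM")   # all three mangroves derived
  expect_equal(res$labels$label[2], "non-convBM")  # methylated everywhere
  # identical binary tables give identical labels through the gene route
  bm <- ifelse(m[-3, ] == "methylated", "BM", "UM")
  gene_lab <- classifyConvergence(inferAncestralStates(bm))
  expect_equal(res$labels$label, gene_lab$label)
})
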
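dmpInput <- function(meth, unmeth, pos = seq_along(meth[[1]])) {
  # meth/unmeth: lists of 6 vectors (3 control then 3 treated)
  lapply(1:6, function(s) makeSites(pos, meth[[s]], unmeth[[s]]))
}

test_that("the DMP GLM matches an independent IRLS fit and flags degeneracy", {
  # strong planted effect: treated ~90% methylated vs control ~10%
  reps <- dmpInput(list(2, 3, 1, 18, 19, 17),
                   list(18, 17, 19, 2, 1, 3))
  res <- callDMPs(reps[1:3], reps[4:6])
  expect_true(res$is_dmp)
  expect_equal(res$direction, "gain")
  expect_lt(res$p_value, 1e-6)
  X <- model.matrix(~ treatment + individual,
                    data.frame(treatment = factor(rep(c("control", "treated"),
                                                      each = 3)),
                               individual = factor(rep(1:3, 2))))
  o <- irlsOracle(X, meth = c(2, 3, 1, 18, 19, 17),
                  unmeth = c(18, 17, 19, 2, 1, 3))
  expect_equal(res$estimate, unname(o$beta[2]), tolerance = 1e-6)
  expect_equal(res$p_value, unname(2 * pnorm(-abs(o$beta[2] / o$se[2]))),
               tolerance = 1e-6)
  # identical proportions in all six samples: no treatment signal
  flat <- dmpInput(as.list(rep(5, 6)), as.list(rep(15, 6)))
  res2 <- callDMPs(flat[1:3], flat[4:6])
  expect_gt(res2$p_value, 0.9)
  expect_false(res2$is_dmp)
  # all-unmethylated site: degenerate, p = 1
  zero <- dmpInput(as.list(rep(0, 6)), as.list(rep(20, 6)))
  res3 <- callDMPs(zero[1:3], zero[4:6])
  expect_true(res3$degenerate)
  expect_equal(res3$p_value, 1)
})

test_that("sites below the coverage floor in any library are not tested", {
  reps <- dmpInput(list(c(2, 2), c(3, 3), c(1, 1),
                        c(18, 9), c(19, 9), c(17, 9)),
                   list(c(18, 2), c(17, 2), c(19, 2),
                        c(2, 1), c(1, 1), c(3, 1)))
  # site 2 has coverage 4 in the first control library
  res <- callDMPs(reps[1:3], reps[4:6])
  expect_equal(nrow(res), 1)
  expect_equal(res$pos, 1L)
})

test_that("separated sites fall back to the likelihood-ratio test", {
  reps <- dmpInput(list(0, 0, 0, 20, 19, 20),
                   list(20, 20, 20, 0, 1, 0))
  res <- callDMPs(reps[1:3], reps[4:6])
  expect_false(res$degenerate)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$direction, "gain")
})

test_that("DMP calling controls the FDR on null data", {
  set.seed(71)
  fprs <- replicate(5, {
    n <- 400
    level <- ifelse(runif(n) < 0.3, 0.8, 0.05)
    reps <- lapply(1:6, function(s) {
      cov <- rpois(n, 20)
      meth <- rbinom(n, cov, level)
      makeSites(seq_len(n), meth, cov - meth)
    })
    res <- callDMPs(reps[1:3], reps[4:6])
    mean(res$is_dmp)
  })
  expect_lte(mean(fprs), 0.05 + 3 * max(sd(fprs) / sqrt(5), 1e-3))
})

test_that("DMP calling has power against a planted shift", {
  set.seed(72)
  n <- 150
  reps <- lapply(1:6, function(s) {
    cov <- rpois(n, 20)
    meth <- rbinom(n, cov, if (s <= 3) 0.1 else 0.6)
    makeSites(seq_len(n), meth, cov - meth)
  })
  res <- callDMPs(reps[1:3], reps[4:6])
  expect_gte(mean(res$is_dmp), 0.8)
  expect_true(all(res$direction[res$is_dmp] == "gain"))
})

test_that("genic enrichment reduces to the hypergeometric closed form", {
  genes <- makeGenes(1, 50, "g1")
  dm <- data.frame(chrom = "chr1", pos = 1:100, strand = "+", context = "CG",
                   estimate = 1, p_value = 0.5, q_value = 0.5,
                   direction = "gain", degenerate = FALSE,
                   is_dmp = c(rep(TRUE, 10), rep(FALSE, 90)),
                   stringsAsFactors = FALSE)
  res <- genicEnrichment(dm, genes)
  expect_equal(res$K, 50)
  expect_equal(res$x, 10)
  expect_equal(res$p_value, choose(50, 10) / choose(100, 10),
               tolerance = 1e-12)
  # no DMPs: p = 1
  dm$is_dmp <- FALSE
  expect_equal(genicEnrichment(dm, genes)$p_value, 1)
})

test_that("DMG calling recovers planted salt-induced class changes", {
  sim <- simulateSaltExperiment(nGenes = 250, seed = 73)
  dmg <- callDMGs(sim$control, sim$treated, sim$genes)
  truth <- sim$truth
  gained <- truth$gene_id[truth$induced_gain]
  stable <- truth$gene_id[!truth$induced_gain & !truth$induced_loss]
  st <- setNames(dmg$status, dmg$gene_id)
  if (length(gained))
    expect_gte(mean(st[gained] == "gained_gbM"), 0.8)
  expect_gte(mean(st[stable] == "unchanged", na.rm = TRUE), 0.95)
  expect_true(all(dmg$status[dmg$class_control == "mCHH" |
                               dmg$class_treated == "mCHH"] == "excluded"))
})

test_that("the contingency analysis reproduces its own arithmetic and null", {
  res <- dmgContingencyCounts(100, 10, 1000, 100)
  expect_equal(res$pct_dmg, c(10, 10))
  expect_equal(res$chi2_p[1], 1, tolerance = 1e-6)
  # equal proportions: statistic 0
  expect_equal(res$chi2_statistic[1], 0, tolerance = 1e-9)
  # stratified path agrees with the count path
  dmgs <- data.frame(
    gene_id = paste0("g", 1:40),
    class_control = rep(c("BM", "UM"), each = 20),
    class_treated = "BM",
    status = rep(c("unchanged", "lost_gbM", "unchanged", "gained_gbM"),
                 each = 10), stringsAsFactors = FALSE)
  conv <- data.frame(gene_id = paste0("g", c(1:5, 21:25)), label = "convBMM")
  out <- dmgContingency(dmgs, conv)
  expect_equal(nrow(out), 4)
  # UM stratum: genes 21..30 unchanged, 31..40 gained; convBMM are 21..25
  um <- out[out$stratum == "UM" & out$group == "convBMM", ]
  expect_equal(um$unchanged, 5)
  expect_equal(um$changed, 0)
  other_um <- out[out$stratum == "UM" & out$group == "others", ]
  expect_equal(other_um$changed, 10)
  expect_equal(other_um$pct_dmg, 200)
})
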
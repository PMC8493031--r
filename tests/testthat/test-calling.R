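test_that("conversion rate pools control counts and ignores their partition", {
  ctl <- makeSites(1:10, meth = rep(0, 10), unmeth = rep(100, 10))
  expect_equal(estimateConversionRate(ctl), 1)
  ctl2 <- makeSites(1:10, meth = c(5, rep(0, 9)), unmeth = c(95, rep(100, 9)))
  expect_equal(estimateConversionRate(ctl2), 0.995)
  # same totals, different partition across sites
  ctl3 <- makeSites(1:10, meth = c(1, 4, rep(0, 8)),
                    unmeth = c(99, 96, rep(100, 8)))
  expect_equal(estimateConversionRate(ctl3), estimateConversionRate(ctl2))
  expect_error(estimateConversionRate(makeSites(1, 0, 0)), "zero total")
})

test_that("site calling applies the binomial test against the conversion null", {
  # a fully unmethylated site has tail probability 1
  s <- makeSample(makeSites(1, 0, 10))
  res <- callSites(s)
  expect_equal(res$p_value, 1)
  expect_equal(res$status, "unmethylated")
  # single saturated site: p equals the closed form (1 - c)^5
  s2 <- makeSample(makeSites(1, 5, 0), conversionRate = 0.995)
  res2 <- callSites(s2)
  expect_equal(res2$p_value, 0.005^5)
  expect_equal(res2$status, "methylated")
  # perfect conversion: any methylated read is impossible under the null
  s3 <- makeSample(makeSites(1:4, c(1, 0, 2, 0), c(9, 10, 8, 10)),
                   conversionRate = 1)
  res3 <- callSites(s3)
  expect_equal(res3$status,
               c("methylated", "unmethylated", "methylated", "unmethylated"))
})

test_that("replicate consensus filters by coverage before voting", {
  call_of <- function(meth, unmeth, status) {
    data.frame(chrom = "chr1", pos = 1L, strand = "+", context = "CG",
               count_meth = meth, count_unmeth = unmeth,
               coverage = meth + unmeth, p_value = 0.5, q_value = 0.5,
               status = status, stringsAsFactors = FALSE)
  }
  # unanimous and covered: retained
  cons <- consensusReplicates(list(call_of(5, 0, "methylated"),
                                   call_of(4, 1, "methylated"),
                                   call_of(5, 1, "methylated")))
  expect_equal(cons$status, "methylated")
  expect_equal(cons$pooled_meth, 14L)
  expect_equal(cons$pooled_total, 16L)
  # majority 2-1: retained with the majority status
  cons2 <- consensusReplicates(list(call_of(5, 0, "methylated"),
                                    call_of(0, 5, "unmethylated"),
                                    call_of(5, 0, "methylated")))
  expect_equal(cons2$status, "methylated")
  # the low-coverage replicate is ignored, the two covered ones agree
  cons3 <- consensusReplicates(list(call_of(1, 1, "unmethylated"),
                                    call_of(8, 1, "methylated"),
                                    call_of(9, 0, "methylated")))
  expect_equal(cons3$status, "methylated")
  expect_equal(cons3$n_eligible, 2L)
  expect_equal(cons3$pooled_total, 18L)  # pooled over eligible replicates only
  # fewer than two eligible replicates: dropped
  cons4 <- consensusReplicates(list(call_of(1, 1, "methylated"),
                                    call_of(2, 0, "methylated"),
                                    call_of(9, 0, "methylated")))
  expect_equal(nrow(cons4), 0)
  expect_error(consensusReplicates(list(call_of(5, 0, "methylated"))),
               "two replicates")
})

test_that("consensus is invariant to replicate order", {
  set.seed(31)
  sim <- simulateMethylome(nGenes = 30, seed = 31)
  calls <- lapply(sim$samples, callSites)
  a <- consensusReplicates(calls)
  b <- consensusReplicates(rev(calls))
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("methylation level is a site proportion and decomposes by chromosome", {
  cons <- data.frame(chrom = rep(c("chr1", "chr2"), c(8, 4)),
                     pos = 1:12, strand = "+", context = "CG",
                     status = rep(c("methylated", "unmethylated"), c(3, 9)),
                     stringsAsFactors = FALSE)
  expect_equal(methylationLevel(cons, "CG"), 0.25)
  expect_true(is.na(methylationLevel(cons, "CHH")))
  # genome-wide level = site-count-weighted mean of per-chromosome levels
  lv1 <- methylationLevel(cons[cons$chrom == "chr1", ], "CG")
  lv2 <- methylationLevel(cons[cons$chrom == "chr2", ], "CG")
  expect_equal(methylationLevel(cons, "CG"), (8 * lv1 + 4 * lv2) / 12)
  # region restriction
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3))
  expect_equal(methylationLevel(cons, "CG", region), 1)
})

test_that("null samples keep the methylated-call fraction at the FDR level", {
  set.seed(41)
  fprs <- replicate(10, {
    n <- 2000
    cov <- rpois(n, 20)
    meth <- rbinom(n, cov, 0.005)
    s <- makeSample(makeSites(seq_len(n), meth, cov - meth))
    calls <- callSites(s)
    mean(calls$status == "methylated")
  })
  mc_se <- sd(fprs) / sqrt(length(fprs))
  expect_lte(mean(fprs), 0.05 + 3 * max(mc_se, 1e-3))
})

test_that("planted methylated sites are recovered with high sensitivity", {
  set.seed(42)
  n <- 2000
  state <- runif(n) < 0.5
  samples <- lapply(1:3, function(r) {
    cov <- rpois(n, 20)
    meth <- rbinom(n, cov, ifelse(state, 0.8 + 0.2 * 0.005, 0.005))
    makeSample(makeSites(seq_len(n), meth, cov - meth), id = paste0("r", r))
  })
  cons <- consensusReplicates(lapply(samples, callSites))
  called <- cons$status[match(which(state), cons$pos)] == "methylated"
  expect_gte(mean(called, na.rm = TRUE), 0.95)
})
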
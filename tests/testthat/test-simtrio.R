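test_that("Mendelian transmission matches expected segregation ratios", {
  set.seed(3)
  expect_true(all(transmitGenotypes(rep(0L, 50), rep(0L, 50)) == 0L))
  expect_true(all(transmitGenotypes(rep(2L, 50), rep(2L, 50)) == 2L))
  # het x het segregates 1:2:1
  pb <- transmitGenotypes(rep(1L, 10000), rep(1L, 10000))
  cs <- chisq.test(table(factor(pb, levels = 0:2)), p = c(.25, .5, .25))
  expect_gt(cs$p.value, 0.01)
  # a son draws his single X allele from the mother only
  son <- transmitGenotypes(rep(1L, 200), rep(0L, 200), chromX = TRUE,
                           probandSex = "male")
  expect_true(all(son == 0L))
  son2 <- transmitGenotypes(rep(0L, 200), rep(2L, 200), chromX = TRUE,
                            probandSex = "male")
  expect_true(all(son2 == 1L))
  # a daughter receives the paternal X plus one maternal allele
  dau <- transmitGenotypes(rep(1L, 200), rep(0L, 200), chromX = TRUE,
                           probandSex = "female")
  expect_true(all(dau == 1L))
})

test_that("the simulator is byte-identical across runs with the same seed", {
  cfg <- smallSimConfig(1, seed = 123, meanExonic = 400)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulateCohort(cfg, d1)
  s2 <- simulateCohort(cfg, d2)
  expect_identical(readLines(s1$vcfPaths[1]), readLines(s2$vcfPaths[1]))
  expect_identical(readLines(s1$freqPath), readLines(s2$freqPath))
})

test_that("an empty cohort still produces valid headers", {
  cfg <- smallSimConfig(0, meanExonic = 400)
  d <- withr::local_tempdir()
  s <- simulateCohort(cfg, d)
  expect_length(s$vcfPaths, 0)
  expect_equal(nrow(s$truth), 0)
  expect_true(file.exists(s$freqPath))
  ft <- readFrequencyTable(s$freqPath)
  expect_true(all(c("chrom", "pos", "ref", "alt", "af") %in% names(ft)))
})

test_that("error-free simulations are Mendelian-consistent everywhere", {
  cfg <- smallSimConfig(2, spikePlan = "none", seed = 21)
  d <- withr::local_tempdir()
  s <- simulateCohort(cfg, d)
  for (p in s$pedigrees) {
    calls <- readTrioVcf(s$vcfPaths[familyId(p)], p)
    ac <- function(id) gtAltCount(genoField(calls, "GT")[, id])
    ok <- mendelOk(ac(fatherId(p)), ac(motherId(p)), ac(probandId(p)))
    expect_true(all(ok))
  }
})

test_that("spiked variants carry their model's genotype configuration", {
  plan <- data.frame(trio = c(1, 1, 2, 2),
                     model = c("de_novo", "x_linked", "ar_homozygous",
                               "ar_compound_het"),
                     consequence = c("nonsense", "missense", "missense",
                                     "missense"),
                     stringsAsFactors = FALSE)
  cfg <- smallSimConfig(2, spikePlan = plan, seed = 31)
  d <- withr::local_tempdir()
  s <- simulateCohort(cfg, d)
  expect_equal(nrow(s$truth), 5)  # compound het contributes two sites
  for (i in seq_len(nrow(s$truth))) {
    tr <- s$truth[i, ]
    p <- s$pedigrees[[match(tr$trioId, vapply(s$pedigrees, familyId, ""))]]
    calls <- readTrioVcf(s$vcfPaths[tr$trioId], p)
    row <- which(variantSites(calls)$chrom == tr$chrom &
                 variantSites(calls)$pos == tr$pos)
    expect_length(row, 1)
    gt <- genoField(calls, "GT")[row, ]
    if (tr$model == "de_novo") {
      expect_equal(unname(gt[c(probandId(p), fatherId(p), motherId(p))]),
                   c("0/1", "0/0", "0/0"))
    } else if (tr$model == "x_linked") {
      expect_equal(unname(gt[probandId(p)]), "1")
      expect_equal(unname(gt[motherId(p)]), "0/1")
      expect_equal(unname(gt[fatherId(p)]), "0")
    } else if (tr$model == "ar_homozygous") {
      expect_equal(unname(gt[probandId(p)]), "1/1")
      expect_true(gtIsHet(gt[fatherId(p)]) && gtIsHet(gt[motherId(p)]))
    }
  }
  # compound het: one site from each parent, same gene
  ch <- s$truth[s$truth$model == "ar_compound_het", ]
  expect_equal(length(unique(ch$gene)), 1)
  # spiked sites are listed with AF below every model threshold
  ft <- readFrequencyTable(s$freqPath)
  key <- paste(ft$chrom, ft$pos)
  spiked <- match(paste(s$truth$chrom, s$truth$pos), key)
  expect_true(all(ft$af[spiked] == 0))
})

test_that("an X-linked spike in a female-proband trio is rejected", {
  plan <- data.frame(trio = 1, model = "x_linked", consequence = "missense",
                     stringsAsFactors = FALSE)
  cfg <- smallSimConfig(1, spikePlan = plan, seed = 5, meanExonic = 400)
  d <- withr::local_tempdir()
  expect_error(simulateCohort(cfg, d, probandSexes = "female"),
               "impossible spike")
})

test_that("background allele frequencies follow the configured Beta law", {
  cfg <- smallSimConfig(1, spikePlan = "none", seed = 77, meanExonic = 6000)
  d <- withr::local_tempdir()
  s <- simulateCohort(cfg, d)
  ft <- readFrequencyTable(s$freqPath)
  ks <- suppressWarnings(ks.test(ft$af, function(q) pbeta(q, 0.8, 0.8)))
  expect_gt(ks$p.value, 0.01)
})

test_that("spike recovery is perfect without error and degrades with it", {
  nT <- 8
  plan <- data.frame(trio = seq_len(nT), model = "de_novo",
                     consequence = "missense", stringsAsFactors = FALSE)
  recoveryAt <- function(err, seed) {
    cfg <- smallSimConfig(nT, spikePlan = plan, seed = seed,
                          errorRate = err, meanExonic = 400)
    d <- withr::local_tempdir()
    s <- simulateCohort(cfg, d)
    txs <- readTranscriptModels(s$gffPath, s$fastaPath)
    ft <- readFrequencyTable(s$freqPath)
    pc <- readPredictorCalls(s$predictorPath)
    hits <- 0
    for (p in s$pedigrees) {
      calls <- readTrioVcf(s$vcfPaths[familyId(p)], p)
      ann <- annotateVariants(calls, txs, ft, pc)
      cand <- prioritizeTrio(calls, ann, p)
      tr <- s$truth[s$truth$trioId == familyId(p), ]
      hit <- paste(tr$chrom, tr$pos) %in% paste(cand$chrom, cand$pos) &
        tr$model %in% cand$model
      hits <- hits + sum(hit)
    }
    hits / nrow(s$truth)
  }
  r0 <- recoveryAt(0, 101)
  r1 <- recoveryAt(0.15, 101)
  r2 <- recoveryAt(0.5, 101)
  expect_equal(r0, 1)                      # clean data: all spikes recovered
  expect_lte(r1, r0)
  expect_lte(r2, r1)
  expect_lt(r2, 1)
})
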
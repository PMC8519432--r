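ped <- trioPed("male")

test_that("the trio quality gate enforces GQ and depth thresholds", {
  # GQ (25,30,40), proband DP 12, parents 8 and 9: pass
  c1 <- makeTrioCalls("0/1", "0/0", "0/0", dp = 12L, gq = 25L)
  c1@dp[1, ] <- c(12L, 8L, 9L); c1@gq[1, ] <- c(25L, 30L, 40L)
  expect_true(trioQualityPass(c1, ped))
  # proband depth 9 fails
  c2 <- makeTrioCalls("0/1", "0/0", "0/0")
  c2@dp[1, 1] <- 9L
  expect_false(trioQualityPass(c2, ped))
  # mother GQ 19 fails
  c3 <- makeTrioCalls("0/1", "0/0", "0/0")
  c3@gq[1, 3] <- 19L
  expect_false(trioQualityPass(c3, ped))
  # missing genotype fails, not errors
  c4 <- makeTrioCalls("0/1", NA, "0/0")
  expect_false(trioQualityPass(c4, ped))
})

test_that("de novo calls require the trio pattern and >10% alternate reads", {
  # proband 0/1 AD (12,8), parents hom-ref: de novo (fraction 0.40)
  dn <- makeTrioCalls("0/1", "0/0", "0/0", dp = 20L,
                      adRefP = 12L, adAltP = 8L)
  expect_true(callDeNovo(dn, ped))
  # fraction 0.08 rejected
  low <- makeTrioCalls("0/1", "0/0", "0/0", dp = 50L,
                       adRefP = 46L, adAltP = 4L)
  expect_false(callDeNovo(low, ped))
  # fraction exactly 0.10 rejected (strict inequality)
  edge <- makeTrioCalls("0/1", "0/0", "0/0", dp = 20L,
                        adRefP = 18L, adAltP = 2L)
  expect_false(callDeNovo(edge, ped))
  # inherited from father: rejected
  inh <- makeTrioCalls("0/1", "0/1", "0/0")
  expect_false(callDeNovo(inh, ped))
  # missing proband AD: retained genotype but fails the read filter
  noAd <- makeTrioCalls("0/1", "0/0", "0/0")
  noAd@adRef[1, 1] <- NA_integer_; noAd@adAlt[1, 1] <- NA_integer_
  expect_false(callDeNovo(noAd, ped))
})

test_that("all 27 trio genotype combinations yield exactly one de novo pattern", {
  gts <- c("0/0", "0/1", "1/1")
  combos <- expand.grid(p = gts, f = gts, m = gts, stringsAsFactors = FALSE)
  calls <- makeTrioCalls(combos$p, combos$f, combos$m, dp = 40L,
                         adRefP = 24L, adAltP = 16L)   # fraction 0.4
  got <- callDeNovo(calls, ped)
  want <- combos$p == "0/1" & combos$f == "0/0" & combos$m == "0/0"
  expect_equal(got, want)
  expect_equal(sum(got), 1L)
})

test_that("autosomal recessive homozygous candidates respect the AF bound", {
  hom <- makeTrioCalls("1/1", "0/1", "0/1")
  annOk <- makeAnn(1, af = 0.01)
  out <- callAutosomalRecessive(hom, annOk, ped)
  expect_equal(out$model, "ar_homozygous")
  # AF 0.05 exceeds the bound
  out2 <- callAutosomalRecessive(hom, makeAnn(1, af = 0.05), ped)
  expect_equal(nrow(out2), 0)
  # AF exactly 0.02 is rejected (strict inequality)
  out3 <- callAutosomalRecessive(hom, makeAnn(1, af = 0.02), ped)
  expect_equal(nrow(out3), 0)
  # synonymous consequence is not impactful
  out4 <- callAutosomalRecessive(hom, makeAnn(1, consequence = "synonymous"), ped)
  expect_equal(nrow(out4), 0)
})

test_that("compound heterozygotes need trans configuration by transmission", {
  trans <- makeTrioCalls(c("0/1", "0/1"), c("0/1", "0/0"), c("0/0", "0/1"))
  out <- callAutosomalRecessive(trans, makeAnn(2, af = 0.01), ped)
  expect_equal(out$model, "ar_compound_het")
  expect_equal(nrow(out), 1)
  expect_false(is.na(out$partnerIdx))
  # both sites from the mother: cis, no candidate
  cis <- makeTrioCalls(c("0/1", "0/1"), c("0/0", "0/0"), c("0/1", "0/1"))
  expect_equal(nrow(callAutosomalRecessive(cis, makeAnn(2, af = 0.01), ped)), 0)
})

test_that("the X-linked model matches the carrier-mother pattern", {
  xcalls <- makeTrioCalls("1", "0", "0/1", chrom = "chrX")
  ann <- makeAnn(1, af = 0.0005)
  expect_true(callXLinked(xcalls, ann, ped))
  # hom-alt dialect for the hemizygous proband
  xc2 <- makeTrioCalls("1/1", "0", "0/1", chrom = "chrX")
  expect_true(callXLinked(xc2, ann, ped))
  # AF 0.002 exceeds the X-linked bound
  expect_false(callXLinked(xcalls, makeAnn(1, af = 0.002), ped))
  # female probands are not handled by this model
  expect_false(callXLinked(xcalls, ann, trioPed("female")))
  # autosomal site never matches
  acalls <- makeTrioCalls("1/1", "0/0", "0/1", chrom = "chr2")
  expect_false(callXLinked(acalls, ann, ped))
})

test_that("prioritization reports models in fixed order with one model per site", {
  calls <- makeTrioCalls(
    gtP = c("0/1", "1/1", "0/1", "0/1", "1"),
    gtF = c("0/0", "0/1", "0/1", "0/0", "0"),
    gtM = c("0/0", "0/1", "0/0", "0/1", "0/1"),
    chrom = c("chr1", "chr2", "chr3", "chr3", "chrX"),
    dp = 40L, adRefP = 24L, adAltP = 16L)
  ann <- makeAnn(5, af = c(0, 0.01, 0.001, 0.001, 0))
  ann$gene <- c("A", "B", "C", "C", "X1")
  cand <- prioritizeTrio(calls, ann, ped)
  expect_equal(cand$model[1], "de_novo")
  expect_setequal(unique(cand$model),
                  c("de_novo", "x_linked", "ar_homozygous", "ar_compound_het"))
  # fixed group order: de novo, then X-linked, then autosomal recessive
  expect_lt(which(cand$model == "x_linked"),
            min(which(cand$model %in% c("ar_homozygous", "ar_compound_het"))))
  # no site appears under two models
  key <- paste(cand$chrom, cand$pos)
  expect_false(anyDuplicated(key) > 0)
  # empty input gives an empty frame
  empty <- prioritizeTrio(calls[0, ], ann[0, ], ped)
  expect_equal(nrow(empty), 0)
})

test_that("within a model, severity then ascending AF orders candidates", {
  calls <- makeTrioCalls(
    gtP = c("0/1", "0/1", "0/1"), gtF = rep("0/0", 3), gtM = rep("0/0", 3),
    chrom = "chr1", dp = 40L, adRefP = 24L, adAltP = 16L)
  ann <- makeAnn(3, af = c(0.001, 0, 0))
  ann$consequence <- c("missense", "nonsense", "missense")
  cand <- prioritizeTrio(calls, ann, ped)
  expect_equal(cand$consequence, c("nonsense", "missense", "missense"))
  expect_equal(cand$populationAf, c(0, 0, 0.001))
})

test_that("tightening any threshold never enlarges the candidate set", {
  set.seed(99)
  n <- 150
  gts <- c("0/0", "0/1", "1/1")
  calls <- makeTrioCalls(sample(gts, n, TRUE), sample(gts, n, TRUE),
                         sample(gts, n, TRUE),
                         chrom = sample(c("chr1", "chr2", "chrX"), n, TRUE),
                         dp = 15L)
  calls@dp[] <- matrix(rpois(n * 3, 15), n, 3)
  calls@gq[] <- matrix(sample(5:99, n * 3, TRUE), n, 3)
  calls@adAlt[] <- matrix(rbinom(n * 3, as.vector(calls@dp), 0.4), n, 3)
  calls@adRef[] <- calls@dp - calls@adAlt
  ann <- makeAnn(n, af = round(runif(n, 0, 0.03), 4),
                 deleterious = sample(c(TRUE, FALSE), n, TRUE))
  ann$gene <- sample(paste0("G", 1:20), n, TRUE)
  ann$consequence <- sample(c("missense", "nonsense", "synonymous", "in_frame"),
                            n, TRUE)
  base <- filterThresholds()
  keysOf <- function(th) {
    cand <- prioritizeTrio(calls, ann, ped, th)
    paste(cand$chrom, cand$pos, cand$model)
  }
  baseKeys <- keysOf(base)
  tighter <- list(
    filterThresholds(minGqTrio = 40),
    filterThresholds(minDpParent = 12),
    filterThresholds(minDpProband = 18),
    filterThresholds(minAltFractionDeNovo = 0.35),
    filterThresholds(maxAfRecessive = 0.005),
    filterThresholds(maxAfXlinked = 0.0001))
  for (th in tighter)
    expect_true(all(keysOf(th) %in% baseKeys))
})
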
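test_that("PED parsing maps complete trios and sex codes", {
  ped <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("FAM1 F1 0 0 1 1",
               "FAM1 M1 0 0 2 1",
               "FAM1 P1 F1 M1 1 2"), ped)
  out <- readPedigree(ped)
  expect_length(out, 1)
  expect_equal(familyId(out[[1]]), "FAM1")
  expect_equal(probandId(out[[1]]), "P1")
  expect_equal(fatherId(out[[1]]), "F1")
  expect_equal(motherId(out[[1]]), "M1")
  expect_equal(probandSex(out[[1]]), "male")
})

test_that("PED parsing keeps multiple families in file order and rejects broken trios", {
  ped <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("FAM1 F1 0 0 1 1", "FAM1 M1 0 0 2 1", "FAM1 P1 F1 M1 2 2",
               "FAM2 F2 0 0 1 1", "FAM2 M2 0 0 2 1", "FAM2 P2 F2 M2 1 2"),
             ped)
  out <- readPedigree(ped)
  expect_equal(vapply(out, familyId, ""), c("FAM1", "FAM2"))
  expect_equal(probandSex(out[[1]]), "female")

  bad <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("FAM1 M1 0 0 2 1", "FAM1 P1 0 M1 1 2"), bad)
  expect_error(readPedigree(bad), "incomplete trio.*FAM1")

  nosex <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F3 F1 0 0 1 1", "F3 M1 0 0 2 1", "F3 P1 F1 M1 0 2"), nosex)
  expect_error(readPedigree(nosex), "sex code")
})

writeTestVcf <- function(lines, samples = c("P1", "F1", "M1")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               lines), path)
  path
}

test_that("trio VCF reading exposes typed genotype records", {
  p <- writeTestVcf(paste("chr1", 100, ".", "A", "G", ".", "PASS", ".",
                          "GT:AD:DP:GQ", "0/1:12,8:20:99", "0/0:19,0:19:80",
                          "0/0:22,0:22:85", sep = "\t"))
  ped <- TrioPedigree("FAM1", "P1", "F1", "M1", "male")
  calls <- readTrioVcf(p, ped)
  expect_equal(nSites(calls), 1)
  expect_equal(unname(genoField(calls, "GT")[1, ]), c("0/1", "0/0", "0/0"))
  expect_equal(unname(genoField(calls, "AD_ALT")[1, "P1"]), 8L)
  expect_equal(unname(genoField(calls, "DP")[1, "M1"]), 22L)
})

test_that("multiallelic records split into biallelic sites with projected AD", {
  p <- writeTestVcf(paste("chr1", 100, ".", "A", "G,T", ".", "PASS", ".",
                          "GT:AD:DP:GQ", "1/2:2,10,5:17:99", "0/1:9,8,0:17:90",
                          "0/0:15,0,0:15:80", sep = "\t"))
  calls <- readTrioVcf(p)
  expect_equal(nSites(calls), 2)
  expect_equal(calls@sites$alt, c("G", "T"))
  # proband 1/2 is het for each split alt
  expect_true(all(gtIsHet(genoField(calls, "GT")[, "P1"])))
  # AD projection conserves the original per-alt observations
  expect_equal(unname(genoField(calls, "AD_ALT")[, "P1"]), c(10L, 5L))
  expect_equal(unname(genoField(calls, "AD_REF")[, "P1"]), c(2L, 2L))
  # parent carrying only alt 2 is hom-ref in the alt-1 record
  expect_equal(unname(genoField(calls, "GT")[, "F1"]), c("0/1", "0/0"))
})

test_that("missing pedigree samples and malformed genotypes are errors", {
  p <- writeTestVcf(paste("chr1", 100, ".", "A", "G", ".", "PASS", ".",
                          "GT:AD:DP:GQ", "0/1:12,8:20:99", "0/0:19,0:19:80",
                          "0/0:22,0:22:85", sep = "\t"))
  ped <- TrioPedigree("FAM1", "P1", "F1", "MX", "male")
  expect_error(readTrioVcf(p, ped), "sample not in VCF")

  bad <- writeTestVcf(paste("chr1", 100, ".", "A", "G", ".", "PASS", ".",
                            "GT:AD:DP:GQ", "0x1:12,8:20:99", "0/0:19,0:19:80",
                            "0/0:22,0:22:85", sep = "\t"))
  expect_error(readTrioVcf(bad), "malformed GT")
})

test_that("missing FORMAT values stay missing, never zero", {
  p <- writeTestVcf(paste("chr1", 100, ".", "A", "G", ".", "PASS", ".",
                          "GT:AD:DP:GQ", "0/1:.:.:99", "./.:19,0:19:80",
                          "0/0:22,0:22:.", sep = "\t"))
  calls <- readTrioVcf(p)
  expect_true(is.na(genoField(calls, "AD_ALT")[1, "P1"]))
  expect_true(is.na(genoField(calls, "DP")[1, "P1"]))
  expect_true(is.na(genoField(calls, "GT")[1, "F1"]))
  expect_true(is.na(genoField(calls, "GQ")[1, "M1"]))
  # a called genotype with missing AD yields an undefined allele fraction
  expect_true(is.na(alleleFraction(genoField(calls, "AD_REF")[1, "P1"],
                                   genoField(calls, "AD_ALT")[1, "P1"])))
})

test_that("VCF round trip reproduces all genotype fields", {
  set.seed(11)
  n <- 200
  gts <- c("0/0", "0/1", "1/1", NA)
  gtM <- matrix(sample(gts, n * 3, replace = TRUE), n, 3,
                dimnames = list(NULL, trioSamples))
  dp <- matrix(rpois(n * 3, 40), n, 3, dimnames = list(NULL, trioSamples))
  adAlt <- matrix(rbinom(n * 3, as.vector(dp), 0.5), n, 3,
                  dimnames = list(NULL, trioSamples))
  adRef <- dp - adAlt
  gq <- matrix(sample(0:99, n * 3, replace = TRUE), n, 3,
               dimnames = list(NULL, trioSamples))
  refs <- sample(c("A", "C", "G", "T", "AT", "GGC"), n, replace = TRUE)
  alts <- vapply(refs, function(r)
    sample(setdiff(c("A", "C", "G", "T"), substr(r, 1, 1)), 1), "")
  sites <- data.frame(chrom = sample(c("chr1", "chrX"), n, TRUE),
                      pos = sort(sample(1:1e6, n)), ref = refs, alt = alts,
                      id = NA_character_, stringsAsFactors = FALSE)
  calls <- TrioCalls(sites, gtM, adRef, adAlt, dp, gq)
  p <- tempfile(fileext = ".vcf")
  writeTrioVcf(calls, p)
  back <- readTrioVcf(p)
  expect_equal(variantSites(back)$pos, variantSites(calls)$pos)
  expect_equal(genoField(back, "GT"), genoField(calls, "GT"))
  expect_equal(genoField(back, "AD_REF"), genoField(calls, "AD_REF"))
  expect_equal(genoField(back, "AD_ALT"), genoField(calls, "AD_ALT"))
  expect_equal(genoField(back, "DP"), genoField(calls, "DP"))
  expect_equal(genoField(back, "GQ"), genoField(calls, "GQ"))
})

test_that("gzipped VCFs round trip transparently", {
  calls <- makeTrioCalls("0/1", "0/0", "0/0")
  p <- tempfile(fileext = ".vcf.gz")
  writeTrioVcf(calls, p)
  back <- readTrioVcf(p)
  expect_equal(genoField(back, "GT"), genoField(calls, "GT"))
})

test_that("allele fractions follow AD arithmetic with undefined degenerate cases", {
  expect_equal(alleleFraction(18, 2), 0.10)
  expect_equal(alleleFraction(12, 8), 0.40)
  expect_true(is.na(alleleFraction(0, 0)))
  expect_true(is.na(alleleFraction(NA, 5)))
})
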
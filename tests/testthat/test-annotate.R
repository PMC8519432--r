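txs <- exampleTranscripts()

test_that("codon arithmetic matches HGVS residue numbering", {
  expect_equal(cdsCodonIndex(1861), data.frame(codon = 621L, offset = 1L))
  expect_equal(cdsCodonIndex(1), data.frame(codon = 1L, offset = 1L))
  expect_equal(cdsCodonIndex(1000), data.frame(codon = 334L, offset = 1L))
  expect_equal(cdsCodonIndex(1826), data.frame(codon = 609L, offset = 2L))
  expect_error(cdsCodonIndex(0), ">= 1")
})

test_that("SNV consequences agree with a translate-and-compare oracle over all 576 cases", {
  skip_if_not_installed("seqinr")
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  nChecked <- 0
  for (codon in codons) {
    tx <- transcriptModel("G", "TX", "chr1", "+",
                          cbind(start = 1L, end = 6L),
                          paste0("ATG", codon))
    for (off in 1:3) {
      refB <- substr(codon, off, off)
      for (altB in setdiff(bases, refB)) {
        got <- classifyCodingChange(tx, 3L + off, refB, altB)$consequence
        newCodon <- codon
        substr(newCodon, off, off) <- altB
        expect_equal(got, oracleSnvClass(codon, newCodon),
                     label = sprintf("%s pos %d %s>%s", codon, off, refB, altB))
        nChecked <- nChecked + 1
      }
    }
  }
  expect_equal(nChecked, 576)
})

test_that("indel frame rule: frameshift iff length difference is not a multiple of 3", {
  set.seed(5)
  tx <- txs[["NM_024665.5"]]
  len <- nchar(txCds(tx))
  for (i in 1:60) {
    L <- sample(1:6, 1)
    pos <- sample(10:(len - 60), 1)
    if (runif(1) < 0.5) {          # deletion
      ref <- substr(txCds(tx), pos, pos + L - 1); alt <- ""
    } else {                        # insertion
      ref <- ""; alt <- paste(sample(c("A", "C", "G", "T"), L, TRUE),
                              collapse = "")
    }
    got <- classifyCodingChange(tx, pos, ref, alt)$consequence
    expect_equal(got == "frameshift", L %% 3 != 0,
                 label = sprintf("pos %d len %d %s", pos, L,
                                 if (ref == "") "ins" else "del"))
  }
})

test_that("the packaged diagnostic variants reproduce their printed types and protein changes", {
  t1 <- loadTable1Candidates()
  for (i in seq_len(nrow(t1))) {
    tx <- txs[[t1$transcript[i]]]
    r <- classifyCdna(tx, t1$nucleotide_change[i])
    expect_equal(r$consequence, t1$consequence[i], label = t1$gene[i])
    if (t1$consequence[i] != "splice_site")
      expect_equal(r$proteinChange, t1$amino_acid_change[i],
                   label = t1$gene[i])
  }
  # the splice-site case: the affected exon spans codons 53..79
  expect_equal(cdsCodonIndex(157)$codon, 53L)
  expect_equal(cdsCodonIndex(237)$codon, 79L)
})

test_that("splice proximity follows the canonical +/-2 rule", {
  tx <- txs[["NM_003079.4"]]            # three exons
  ex <- txExons(tx)
  donor <- ex[2, 2]                     # end of exon 2 (CDS 237)
  expect_equal(classifySpliceProximity(tx, donor + 1L), "splice_site")
  expect_equal(classifySpliceProximity(tx, donor + 2L), "splice_site")
  expect_equal(classifySpliceProximity(tx, donor + 10L), "intronic")
  acceptor <- ex[3, 1]
  expect_equal(classifySpliceProximity(tx, acceptor - 2L), "splice_site")
  expect_equal(classifySpliceProximity(tx, donor), "coding")
  expect_equal(classifySpliceProximity(tx, min(ex) - 100L), "other")
})

test_that("population AF lookup is exact-key with absence meaning novel", {
  ft <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                   af = 0.005, stringsAsFactors = FALSE)
  expect_equal(lookupPopulationAF("chr1", 100, "A", "G", ft), 0.005)
  expect_equal(lookupPopulationAF("1", 100, "A", "G", ft), 0.005)  # dialects
  expect_equal(lookupPopulationAF("chr1", 101, "A", "G", ft), 0)
  expect_equal(lookupPopulationAF("chr1", 100, "A", "T", ft), 0)   # other alt
})

test_that("predictor consensus is a majority rule over damaging calls", {
  expect_true(predictorConsensus(c(P1 = "D", P2 = "Prob. DA", P3 = "tolerated")))
  expect_true(is.na(predictorConsensus(character(0))))
  expect_false(predictorConsensus(c(P1 = "tolerated", P2 = "neutral")))
  expect_true(predictorConsensus(c(P1 = "H", P2 = "neutral")))  # 1/2 is half
  expect_error(predictorConsensus(c(P1 = "meh")), "accepted labels")
})

test_that("genomic annotation handles both strands and indels", {
  # plus strand: SYNGAP1 c.1861C>T from genomic coordinates
  sy <- txs[["NM_006772.2"]]
  g <- cdsToGenomic(sy, 1861L)
  sites <- data.frame(chrom = txChrom(sy), pos = g, ref = "C", alt = "T",
                      stringsAsFactors = FALSE)
  ann <- annotateVariants(sites, txs)
  expect_equal(ann$consequence, "nonsense")
  expect_equal(ann$proteinChange, "p.Arg621*")
  expect_equal(ann$cdnaChange, "c.1861C>T")

  # minus strand: KCNQ3 c.688C>T appears as G>A on the genome
  kc <- txs[["NM_004519.3"]]
  g <- cdsToGenomic(kc, 688L)
  sites <- data.frame(chrom = txChrom(kc), pos = g, ref = "G", alt = "A",
                      stringsAsFactors = FALSE)
  ann <- annotateVariants(sites, txs)
  expect_equal(ann$consequence, "missense")
  expect_equal(ann$proteinChange, "p.Arg230Cys")

  # anchored deletion on the plus strand: SATB2 c.1826delA
  sa <- txs[["NM_001172509.1"]]
  g <- cdsToGenomic(sa, 1825L)
  anchored <- data.frame(chrom = txChrom(sa), pos = g,
                         ref = substr(txCds(sa), 1825, 1826),
                         alt = substr(txCds(sa), 1825, 1825),
                         stringsAsFactors = FALSE)
  ann <- annotateVariants(anchored, txs)
  expect_equal(ann$consequence, "frameshift")
  expect_equal(ann$codon, 609L)
})

test_that("transcript models round trip through GFF3 + FASTA", {
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fa")
  writeTranscriptModels(txs, gff, fa)
  back <- readTranscriptModels(gff, fa)
  expect_setequal(names(back), names(txs))
  for (id in names(txs)) {
    expect_equal(txCds(back[[id]]), txCds(txs[[id]]), label = id)
    expect_equal(txExons(back[[id]]), txExons(txs[[id]]), label = id)
    expect_equal(txStrand(back[[id]]), txStrand(txs[[id]]), label = id)
    expect_equal(txGene(back[[id]]), txGene(txs[[id]]), label = id)
  }
})

test_that("coordinate mapping is a strand-aware bijection over the CDS", {
  for (id in c("NM_003079.4", "NM_004519.3")) {   # multi-exon and minus strand
    tx <- txs[[id]]
    cdsPos <- seq_len(nchar(txCds(tx)))
    g <- cdsToGenomic(tx, cdsPos)
    expect_false(anyNA(g))
    expect_equal(genomicToCds(tx, g), cdsPos)
  }
})

test_that("a reference mismatch against the transcript is an error", {
  tx <- txs[["NM_006772.2"]]
  wrong <- setdiff(c("A", "C", "G", "T"), substr(txCds(tx), 1861, 1861))[1]
  expect_error(classifyCodingChange(tx, 1861, wrong, "T"),
               "transcript/variant inconsistency")
})

test_that("the shipped synthetic transcript fixtures match the in-code builder", {
  gff <- system.file("extdata", "synthetic_transcripts.gff3",
                     package = "TrioExome", mustWork = TRUE)
  fa <- system.file("extdata", "synthetic_transcripts.fa",
                    package = "TrioExome", mustWork = TRUE)
  shipped <- readTranscriptModels(gff, fa)
  built <- exampleTranscripts()
  expect_setequal(names(shipped), names(built))
  for (id in names(built)) {
    expect_equal(txCds(shipped[[id]]), txCds(built[[id]]), label = id)
    expect_equal(txExons(shipped[[id]]), txExons(built[[id]]), label = id)
  }
})
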
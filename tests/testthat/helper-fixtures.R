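# Shared builders for the test suite. Fixtures are constructed in code;
# nothing binary is stored.

trioSamples <- c("PB", "FA", "MO")
trioPed <- function(sex = "male") TrioPedigree("FAM", "PB", "FA", "MO", sex)

# Build a TrioCalls object from genotype strings; AD defaults consistent
# with the genotype at the given depth, GQ high.
makeTrioCalls <- function(gtP, gtF, gtM,
                          chrom = "chr1", pos = NULL, ref = "A", alt = "G",
                          dp = 40L, gq = 99L,
                          adAltP = NULL, adRefP = NULL) {
  n <- length(gtP)
  if (is.null(pos)) pos <- seq(100L, by = 10L, length.out = n)
  sites <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      id = NA_character_, stringsAsFactors = FALSE)
  gt <- cbind(PB = gtP, FA = gtF, MO = gtM)
  dpM <- matrix(rep_len(dp, n * 3L), n, 3, dimnames = list(NULL, trioSamples))
  gqM <- matrix(rep_len(gq, n * 3L), n, 3, dimnames = list(NULL, trioSamples))
  defaultAlt <- function(g, d) {
    ac <- gtAltCount(g); pl <- gtPloidy(g)
    out <- ifelse(is.na(ac), NA_integer_,
                  as.integer(round(d * ac / pmax(pl, 1L))))
    out
  }
  adAlt <- cbind(PB = defaultAlt(gtP, dpM[, 1]), FA = defaultAlt(gtF, dpM[, 2]),
                 MO = defaultAlt(gtM, dpM[, 3]))
  if (!is.null(adAltP)) adAlt[, 1] <- adAltP
  adRef <- dpM - adAlt
  if (!is.null(adRefP)) adRef[, 1] <- adRefP
  TrioCalls(sites, gt, adRef, adAlt, dpM, gqM)
}

# Uniform annotation frame for synthetic calls.
makeAnn <- function(n, gene = "G1", consequence = "missense", af = 0,
                    deleterious = TRUE) {
  data.frame(gene = rep_len(gene, n), transcriptId = "TX1",
             region = "coding", consequence = rep_len(consequence, n),
             cdnaChange = NA_character_, proteinChange = NA_character_,
             codon = NA_integer_, populationAf = rep_len(af, n),
             predictorDeleterious = rep_len(deleterious, n),
             stringsAsFactors = FALSE)
}

# Independent translate-and-compare SNV classifier built on seqinr
# (the implementation path uses Biostrings).
oracleSnvClass <- function(oldCodon, newCodon) {
  tr <- function(cod) seqinr::translate(strsplit(cod, "")[[1]])
  a <- tr(oldCodon); b <- tr(newCodon)
  if (a == b) "synonymous"
  else if (b == "*") "nonsense"
  else if (a == "*") "unknown"
  else "missense"
}

# Independent Mendelian-consistency check on alternate-allele counts.
mendelOk <- function(fa, mo, pb) {
  patSet <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  ok <- logical(length(fa))
  for (i in seq_along(fa)) {
    pats <- patSet[[as.character(fa[i])]]
    mats <- patSet[[as.character(mo[i])]]
    ok[i] <- pb[i] %in% outer(pats, mats, `+`)
  }
  ok
}

# Apply a (pos, ref, alt) representation to a context string.
applyVariant <- function(ctx, pos, ref, alt) {
  paste0(substr(ctx, 1, pos - 1), alt,
         substr(ctx, pos + nchar(ref), nchar(ctx)))
}

# Small scaled-down simulator configuration (background size is a test
# sample-size choice; thresholds and rates stay at defaults).
smallSimConfig <- function(nTrios, spikePlan = NULL, seed = 1,
                           errorRate = 0, meanExonic = 1200) {
  simConfig(nTrios = nTrios,
            meanExonicPerIndividual = meanExonic,
            classMix = round(c(missense = 0.452, lof = 0.0166,
                               non_frameshift = 0.0112,
                               synonymous = 0.501) * meanExonic),
            genotypingErrorRate = errorRate,
            spikePlan = spikePlan, seed = seed)
}
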
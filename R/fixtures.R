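# Packaged example transcripts. These are SYNTHETIC sequences: real
# transcript sequences are not bundled. Each model is constructed so that
# the codons named by the packaged candidate-table fixture hold (e.g.
# codon 621 of the SYNGAP1 model is CGA, so c.1861C>T yields p.Arg621*),
# which anchors the worked examples without shipping reference data.
# Everything else in the sequences is deterministic pseudo-random filler.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, .STOP_CODONS)
})

# n random non-stop codons
.randCodons <- function(n) sample(.SENSE_CODONS, n, replace = TRUE)

# Rejection search: re-randomize ref-frame codons downstream of a
# frameshifting deletion until the shifted reading frame reaches its first
# stop exactly `fsStop` codons after the first affected codon (counting
# that codon as 1), while the reference frame stays stop-free.
.fsTailSearch <- function(codons, delPos, delLen, firstCodon, fsStop,
                          searchFrom = firstCodon + 1L, wantAA = NULL,
                          maxTries = 50000L) {
  reach <- firstCodon + fsStop + 2L
  idx <- searchFrom:min(reach, length(codons) - 1L)
  for (try in seq_len(maxTries)) {
    codons[idx] <- .randCodons(length(idx))
    cds <- paste(codons, collapse = "")
    mut <- paste0(substr(cds, 1, delPos - 1L),
                  substr(cds, delPos + delLen, nchar(cds)))
    mutAA <- translateCds(substr(mut, 1, nchar(mut) - nchar(mut) %% 3))
    if (!is.null(wantAA) && mutAA[firstCodon] != wantAA) next
    stops <- which(mutAA == "*")
    stops <- stops[stops >= firstCodon]
    if (length(stops) && stops[1] == firstCodon + fsStop - 1L)
      return(codons)
  }
  stop("frameshift tail construction failed")   # not reachable in practice
}

.buildTx <- function(gene, id, chrom, strand, nCodons, fixed = list(),
                     exonLens = NULL, gStart = 5000L, fs = NULL) {
  codons <- .randCodons(nCodons)
  codons[1] <- "ATG"
  codons[nCodons] <- "TAA"
  for (k in names(fixed)) codons[as.integer(k)] <- fixed[[k]]
  if (!is.null(fs))
    codons <- do.call(.fsTailSearch, c(list(codons = codons), fs))
  cds <- paste(codons, collapse = "")
  len <- nchar(cds)
  if (is.null(exonLens)) exonLens <- len
  stopifnot(sum(exonLens) == len)
  starts <- integer(length(exonLens)); ends <- integer(length(exonLens))
  g <- gStart
  for (e in seq_along(exonLens)) {
    starts[e] <- g
    ends[e] <- g + exonLens[e] - 1L
    g <- ends[e] + 1L + 500L   # 500 nt introns
  }
  transcriptModel(gene, id, chrom, strand,
                  cbind(start = starts, end = ends), cds)
}

#' Packaged synthetic example transcripts
#'
#' Deterministically generated transcript models for the eleven genes of
#' the packaged candidate-table fixture (plus the HSF2 candidate gene).
#' Key codons are pinned so that the fixture's c. descriptions reproduce
#' their printed protein changes; see the package vignette. The models are
#' also shipped as GFF3 + CDS FASTA under `inst/extdata/` (files prefixed
#' `synthetic_`), written by [writeTranscriptModels()]; this function is
#' the source of truth.
#'
#' @return named list of [TranscriptModel-class], keyed by transcript id.
#' @examples
#' txs <- exampleTranscripts()
#' classifyCodingChange(txs[["NM_006772.2"]], 1861, "C", "T")
#' @export
exampleTranscripts <- function() {
  withPrivateSeed(20211015L, {
    txs <- list(
      # VAMP2: codon 43 GTG (Val); codon 44 starts G so c.128_130delTGG is
      # a clean single-residue deletion (p.Val43del)
      .buildTx("VAMP2", "NM_014232.2", "chr1", "+", 117,
               fixed = list(`43` = "GTG", `44` = "GAA")),
      # SYNGAP1: codon 621 CGA -> c.1861C>T gives TGA (p.Arg621*)
      .buildTx("SYNGAP1", "NM_006772.2", "chr2", "+", 640,
               fixed = list(`621` = "CGA")),
      # TBL1XR1: codon 334 TGT (Cys334Arg), codon 348 CAC (His348Arg)
      .buildTx("TBL1XR1", "NM_024665.5", "chr3", "+", 515,
               fixed = list(`334` = "TGT", `348` = "CAC")),
      # SATB2: codon 609 GAC; c.1826delA shifts to Ala and stops 15 codons
      # in (p.Asp609Alafs*15); tail constructed by search
      .buildTx("SATB2", "NM_001172509.1", "chr4", "+", 640,
               fixed = list(`609` = "GAC"),
               fs = list(delPos = 1826L, delLen = 1L, firstCodon = 609L,
                         fsStop = 15L, wantAA = "A")),
      # KCNQ3 (minus strand): codon 230 CGC -> c.688C>T gives p.Arg230Cys
      .buildTx("KCNQ3", "NM_004519.3", "chr5", "-", 440,
               fixed = list(`230` = "CGC")),
      # SMARCE1: exon 2 spans CDS 157..237 (codons 53..79, Ala53/Lys79);
      # c.237+1 is the donor +1 of intron 2
      .buildTx("SMARCE1", "NM_003079.4", "chr6", "+", 250,
               fixed = list(`53` = "GCA", `79` = "AAA"),
               exonLens = c(156L, 81L, 250L * 3L - 237L)),
      # SPTAN1: codons 2198 CTG / 2199 CAG -> c.6592_6597dupCTGCAG gives
      # p.Leu2198_Gln2199dup
      # codon 2200 pinned off Leu/Gln so the duplication naming is exact
      .buildTx("SPTAN1", "NM_001130438.2", "chr7", "+", 2210,
               fixed = list(`2198` = "CTG", `2199` = "CAG", `2200` = "GAT")),
      # ASXL3: codon 1036 CGA -> c.3106C>T gives p.Arg1036*
      .buildTx("ASXL3", "NM_030632.2", "chr8", "+", 1045,
               fixed = list(`1036` = "CGA")),
      # LAS1L on chrX: codon 413 GGA -> c.1237G>A gives p.Gly413Arg
      .buildTx("LAS1L", "NM_031206.4", "chrX", "+", 420,
               fixed = list(`413` = "GGA")),
      # SLC6A1: codon 297 GGA -> c.889G>A gives p.Gly297Arg
      .buildTx("SLC6A1", "NM_003042.3", "chr9", "+", 310,
               fixed = list(`297` = "GGA")),
      # HSF2: codon 152 AGT (Ser), codon 153 GAG; deleting c.456_459TGAG
      # shifts to Arg with the stop 40 codons in (p.Ser152Argfs*40);
      # codon 154 pinned to start with G so the shifted codon is AGG (Arg)
      .buildTx("HSF2", "NM_004506.3", "chr10", "+", 200,
               fixed = list(`152` = "AGT", `153` = "GAG", `154` = "GGT"),
               fs = list(delPos = 456L, delLen = 4L, firstCodon = 152L,
                         fsStop = 40L, searchFrom = 155L, wantAA = "R"))
    )
    names(txs) <- vapply(txs, txId, character(1))
    txs
  })
}
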
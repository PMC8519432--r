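# Transcript models: CDS exon structures (GFF3 subset) plus CDS sequences
# (FASTA), and the genomic <-> CDS coordinate arithmetic used by the
# consequence annotator. HGVS convention: CDS positions are 1-based with
# position 1 the A of the ATG.

#' Translate a CDS character string
#'
#' Splits the CDS into codons and translates with the standard genetic
#' code ([Biostrings::GENETIC_CODE]). Returns the amino-acid vector in
#' one-letter code, including any stop (`"*"`).
#'
#' @param cds CDS sequence (character scalar, length a multiple of 3).
#' @return character vector of one-letter amino acids.
#' @export
translateCds <- function(cds) {
  n <- nchar(cds)
  if (n == 0) return(character(0))
  if (n %% 3 != 0) stop("CDS length is not a multiple of 3")
  codons <- substring(cds, seq(1, n - 2, 3), seq(3, n, 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("CDS contains non-ACGT codons")
  aa
}

# Protein up to (and excluding) the first stop codon, as a character vector.
proteinOf <- function(cds) {
  aa <- translateCds(substr(cds, 1, nchar(cds) - nchar(cds) %% 3))
  stop1 <- which(aa == "*")[1]
  if (!is.na(stop1)) aa <- aa[seq_len(stop1 - 1L)]
  aa
}

# Exon widths in transcription order (5' -> 3' of the coding strand).
.txOrderedExons <- function(tx) {
  ex <- tx@exons
  if (tx@strand == "-") ex[rev(seq_len(nrow(ex))), , drop = FALSE] else ex
}

#' Map a genomic position to a CDS coordinate
#'
#' Strand-aware: on minus-strand transcripts CDS position 1 corresponds to
#' the highest genomic coordinate of the last exon. Returns `NA` for
#' positions outside the CDS exons.
#'
#' @param tx a [TranscriptModel-class].
#' @param gpos integer vector of 1-based genomic positions.
#' @return integer vector of 1-based CDS positions (`NA` if non-exonic).
#' @export
genomicToCds <- function(tx, gpos) {
  ex <- .txOrderedExons(tx)
  w <- ex[, 2] - ex[, 1] + 1L
  offs <- c(0L, cumsum(w))[seq_len(nrow(ex))]
  out <- rep(NA_integer_, length(gpos))
  for (e in seq_len(nrow(ex))) {
    hit <- !is.na(gpos) & gpos >= ex[e, 1] & gpos <= ex[e, 2]
    if (!any(hit)) next
    out[hit] <- if (tx@strand == "+") offs[e] + (gpos[hit] - ex[e, 1] + 1L)
                else offs[e] + (ex[e, 2] - gpos[hit] + 1L)
  }
  as.integer(out)
}

#' Map a CDS coordinate to a genomic position
#'
#' Inverse of [genomicToCds()].
#'
#' @param tx a [TranscriptModel-class].
#' @param cdsPos integer vector of 1-based CDS positions.
#' @return integer vector of genomic positions (`NA` if out of range).
#' @export
cdsToGenomic <- function(tx, cdsPos) {
  ex <- .txOrderedExons(tx)
  w <- ex[, 2] - ex[, 1] + 1L
  ends <- cumsum(w)
  offs <- c(0L, ends)[seq_len(nrow(ex))]
  out <- rep(NA_integer_, length(cdsPos))
  for (e in seq_len(nrow(ex))) {
    hit <- !is.na(cdsPos) & cdsPos > offs[e] & cdsPos <= ends[e]
    if (!any(hit)) next
    within <- cdsPos[hit] - offs[e]
    out[hit] <- if (tx@strand == "+") ex[e, 1] + within - 1L
                else ex[e, 2] - within + 1L
  }
  as.integer(out)
}

#' Read transcript models from GFF3 + CDS FASTA
#'
#' The GFF3 (parsed with [rtracklayer::import()]) must carry `CDS`
#' features with `ID`/`Parent` or `transcript_id` attributes and a
#' `gene_name`/`gene` attribute; the FASTA holds one CDS sequence per
#' transcript, named by transcript id.
#'
#' @param gffPath GFF3 path.
#' @param fastaPath CDS FASTA path.
#' @return named list of [TranscriptModel-class] (names are transcript ids).
#' @export
readTranscriptModels <- function(gffPath, fastaPath) {
  gr <- rtracklayer::import(gffPath, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  mc <- S4Vectors::mcols(gr)
  txIds <- if (!is.null(mc$transcript_id)) as.character(mc$transcript_id)
           else vapply(mc$Parent, function(p) as.character(p)[1], character(1))
  genes <- if (!is.null(mc$gene_name)) as.character(mc$gene_name)
           else if (!is.null(mc$gene)) as.character(mc$gene)
           else txIds
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  # FASTA names may carry descriptions after whitespace
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- list()
  for (id in unique(txIds)) {
    sel <- txIds == id
    if (!id %in% names(seqs))
      stop(sprintf("transcript %s has no CDS sequence in %s", id, fastaPath))
    out[[id]] <- transcriptModel(
      gene = genes[sel][1], txId = id,
      chrom = as.character(GenomicRanges::seqnames(gr[sel]))[1],
      strand = as.character(GenomicRanges::strand(gr[sel]))[1],
      exons = cbind(start = GenomicRanges::start(gr[sel]),
                    end = GenomicRanges::end(gr[sel])),
      cds = as.character(seqs[[id]]))
  }
  out
}

#' Write transcript models as GFF3 + CDS FASTA
#'
#' @param txs named list of [TranscriptModel-class].
#' @param gffPath,fastaPath output paths.
#' @return invisibly, `c(gffPath, fastaPath)`.
#' @export
writeTranscriptModels <- function(txs, gffPath, fastaPath) {
  grs <- lapply(txs, function(tx) {
    ex <- tx@exons
    GenomicRanges::GRanges(
      seqnames = tx@chrom,
      ranges = IRanges::IRanges(start = ex[, 1], end = ex[, 2]),
      strand = tx@strand,
      type = "CDS",
      ID = paste0(tx@txId, ".cds", seq_len(nrow(ex))),
      transcript_id = tx@txId,
      gene_name = tx@gene)
  })
  # the synthetic chromosomes carry no shared Seqinfo; the merge warning
  # and absent CDS phase are expected for these minimal models
  gr <- suppressWarnings(do.call(c, unname(grs)))
  suppressWarnings(rtracklayer::export(gr, gffPath, format = "gff3"))
  seqs <- Biostrings::DNAStringSet(vapply(txs, txCds, character(1)))
  names(seqs) <- vapply(txs, txId, character(1))
  Biostrings::writeXStringSet(seqs, fastaPath)
  invisible(c(gffPath, fastaPath))
}
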